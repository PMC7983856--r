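#' GenePop input and output
#'
#' The GenePop text format stores codominant genotypes as concatenated 2- or
#' 3-digit allele codes ("0101" or "001001"), with "00"/"000" marking a
#' missing allele and `pop` lines separating population (here: family)
#' blocks. Code width is auto-detected per file and must be consistent.
#'
#' @name genepop
NULL

#' Read a GenePop file
#'
#' @param path file path.
#' @return object of class `genepop`: list with `title`, `loci`, and `pops`
#'   — a list of blocks, each with `ids` (character) and `genotypes`
#'   (a genotype matrix).
#' @export
read_genepop <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (length(lines) < 2L) stop("GenePop file too short: ", path, call. = FALSE)
  title <- lines[1L]
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1L]
  if (is.na(first_pop)) {
    # header-only file (no pop blocks): legal for an empty collection
    first_pop <- length(lines) + 1L
  }
  locus_lines <- trimws(lines[2:(first_pop - 1L)])
  loci <- unlist(strsplit(locus_lines[nzchar(locus_lines)], ","))
  loci <- trimws(loci)
  if (!length(loci)) stop("GenePop file lists no loci: ", path, call. = FALSE)
  n_loci <- length(loci)

  pops <- list()
  code_width <- NA_integer_
  cur_ids <- character(0)
  cur_geno <- list()
  flush <- function() {
    if (length(cur_geno)) {
      g <- genotype_matrix(do.call(rbind, cur_geno), loci)
      pops[[length(pops) + 1L]] <<- list(ids = cur_ids, genotypes = g)
    }
    cur_ids <<- character(0); cur_geno <<- list()
  }
  for (i in seq_along(lines)) {
    if (i < first_pop) next
    if (is_pop[i]) { flush(); next }
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    parts <- strsplit(line, ",", fixed = TRUE)[[1L]]
    if (length(parts) < 2L) {
      stop(sprintf("line %d: expected 'id , genotypes' in %s", i, path),
           call. = FALSE)
    }
    id <- trimws(parts[1L])
    entries <- strsplit(trimws(paste(parts[-1L], collapse = ",")),
                        "[[:space:]]+")[[1L]]
    if (length(entries) != n_loci) {
      stop(sprintf("line %d: individual '%s' has %d loci, expected %d",
                   i, id, length(entries), n_loci), call. = FALSE)
    }
    widths <- unique(nchar(entries))
    if (length(widths) != 1L || !(widths %in% c(4L, 6L))) {
      stop(sprintf("line %d: inconsistent allele code width", i),
           call. = FALSE)
    }
    w <- widths %/% 2L
    if (is.na(code_width)) code_width <- w
    if (w != code_width) {
      stop(sprintf("line %d: mixed allele code widths (%d vs %d digits)",
                   i, w, code_width), call. = FALSE)
    }
    a1 <- as.integer(substr(entries, 1L, w))
    a2 <- as.integer(substr(entries, w + 1L, 2L * w))
    if (any(is.na(a1)) || any(is.na(a2))) {
      stop(sprintf("line %d: non-numeric allele code", i), call. = FALSE)
    }
    half <- xor(a1 == 0L, a2 == 0L)
    if (any(half)) {
      stop(sprintf("line %d: half-missing genotype at locus %s",
                   i, loci[which(half)[1L]]), call. = FALSE)
    }
    a1[a1 == 0L] <- NA_integer_
    a2[a2 == 0L] <- NA_integer_
    g <- as.vector(rbind(a1, a2))
    cur_ids <- c(cur_ids, id)
    cur_geno[[length(cur_geno) + 1L]] <- g
  }
  flush()
  structure(list(title = title, loci = loci, pops = pops,
                 code_width = if (is.na(code_width)) 3L else code_width),
            class = "genepop")
}

#' Write a GenePop file
#'
#' @param collection a `genepop` object (see [read_genepop()]) or the result
#'   of [arrays_to_genepop()].
#' @param path output path.
#' @param code_width allele code width in digits (2 or 3).
#' @return `path`, invisibly.
#' @export
write_genepop <- function(collection, path, code_width = 3L) {
  stopifnot(inherits(collection, "genepop"), code_width %in% c(2L, 3L))
  maxcode <- 10L^code_width - 1L
  fmt <- sprintf("%%0%dd%%0%dd", code_width, code_width)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(collection$title, con)
  writeLines(collection$loci, con)
  for (blk in collection$pops) {
    writeLines("pop", con)
    g <- blk$genotypes
    for (r in seq_len(nrow(g))) {
      entries <- character(length(collection$loci))
      for (l in seq_along(collection$loci)) {
        cc <- locus_cols(l)
        a <- g[r, cc[1L]]; b <- g[r, cc[2L]]
        if (is.na(a)) { entries[l] <- sprintf(fmt, 0L, 0L); next }
        if (a > maxcode || b > maxcode) {
          stop(sprintf("allele code %d at locus %s exceeds %d-digit width",
                       max(a, b), collection$loci[l], code_width),
               call. = FALSE)
        }
        entries[l] <- sprintf(fmt, a, b)
      }
      writeLines(paste0(blk$ids[r], " ,  ", paste(entries, collapse = " ")),
                 con)
    }
  }
  invisible(path)
}

#' Convert progeny arrays to a GenePop collection
#'
#' One `pop` block per family; offspring only (GenePop has no slot for a
#' maternal genotype — use the progeny-table TSV dialect to carry mothers).
#'
#' @param arrays list of [progeny_array()].
#' @param title title line for the file.
#' @return a `genepop` object.
#' @export
arrays_to_genepop <- function(arrays, title = "matingkit progeny arrays") {
  stopifnot(length(arrays) >= 1L)
  loci <- arrays[[1L]]$loci
  pops <- lapply(arrays, function(a) {
    stopifnot(identical(a$loci, loci))
    list(ids = sprintf("%s_%02d", a$family, seq_len(nrow(a$offspring))),
         genotypes = a$offspring)
  })
  structure(list(title = title, loci = loci, pops = pops, code_width = 3L),
            class = "genepop")
}

#' Convert a GenePop collection to progeny arrays
#'
#' Each `pop` block becomes one family (mothers absent, to be inferred).
#' Family ids are taken from the shared prefix of individual ids when one
#' exists, else `fam01`, `fam02`, ...
#'
#' @param collection a `genepop` object.
#' @param population population id to stamp on the arrays.
#' @return list of [progeny_array()].
#' @export
genepop_to_arrays <- function(collection, population = "pop1") {
  stopifnot(inherits(collection, "genepop"))
  lapply(seq_along(collection$pops), function(i) {
    blk <- collection$pops[[i]]
    ids <- blk$ids
    fam <- sub("_[0-9]+$", "", ids[1L])
    if (!nzchar(fam) || !all(startsWith(ids, fam))) {
      fam <- sprintf("fam%02d", i)
    }
    progeny_array(fam, population, blk$genotypes, collection$loci)
  })
}
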