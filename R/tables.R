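#' Tabular dialects
#'
#' All tables are UTF-8, LF-terminated TSV. Genotypes in the progeny-table
#' dialect are written per locus as `a1/a2` with `.` for a missing locus;
#' half-missing entries are rejected. Readers validate and report the
#' offending row rather than coercing silently.
#'
#' @name io_tables
NULL

read_tsv_strict <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "", comment.char = "")
}

write_tsv <- function(df, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

need_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
}

parse_geno_field <- function(x, row, locus) {
  if (x == ".") return(c(NA_integer_, NA_integer_))
  parts <- strsplit(x, "/", fixed = TRUE)[[1L]]
  ab <- suppressWarnings(as.integer(parts))
  if (length(ab) != 2L || any(is.na(ab))) {
    stop(sprintf("row %d, locus %s: malformed genotype '%s' (want 'a1/a2' or '.')",
                 row, locus, x), call. = FALSE)
  }
  ab
}

format_geno_field <- function(a, b) {
  ifelse(is.na(a), ".", paste0(a, "/", b))
}

#' Read a family-structured progeny genotype table
#'
#' TSV columns: `population`, `family`, `individual`,
#' `role` (`mother`/`offspring`), then one column per locus holding `a1/a2`
#' or `.` (missing). At most one mother row per family.
#'
#' @param path file path.
#' @return list of [progeny_array()].
#' @export
read_progeny_table <- function(path) {
  df <- read_tsv_strict(path)
  need_cols(df, c("population", "family", "individual", "role"), path)
  loci <- setdiff(names(df), c("population", "family", "individual", "role"))
  if (!length(loci)) stop(path, ": no locus columns", call. = FALSE)
  bad_role <- !df$role %in% c("mother", "offspring")
  if (any(bad_role)) {
    stop(sprintf("row %d: role must be 'mother' or 'offspring'",
                 which(bad_role)[1L]), call. = FALSE)
  }
  keys <- paste(df$population, df$family, sep = "\r")
  out <- list()
  for (key in unique(keys)) {
    rows <- which(keys == key)
    sub <- df[rows, , drop = FALSE]
    g <- matrix(NA_integer_, nrow(sub), 2L * length(loci))
    for (j in seq_along(loci)) {
      for (r in seq_len(nrow(sub))) {
        g[r, locus_cols(j)] <- parse_geno_field(as.character(sub[[loci[j]]][r]),
                                                rows[r], loci[j])
      }
    }
    is_mom <- sub$role == "mother"
    if (sum(is_mom) > 1L) {
      stop(sprintf("family %s: duplicate mother rows (rows %s)",
                   sub$family[1L],
                   paste(rows[is_mom], collapse = ", ")), call. = FALSE)
    }
    mother <- if (any(is_mom)) g[which(is_mom), ] else NULL
    off <- g[!is_mom, , drop = FALSE]
    if (!nrow(off)) {
      stop(sprintf("family %s has no offspring rows", sub$family[1L]),
           call. = FALSE)
    }
    out[[length(out) + 1L]] <- progeny_array(
      sub$family[1L], sub$population[1L], off, loci, mother = mother)
  }
  out
}

#' Write progeny arrays in the tabular dialect
#'
#' @param arrays list of [progeny_array()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_progeny_table <- function(arrays, path) {
  stopifnot(length(arrays) >= 1L)
  loci <- arrays[[1L]]$loci
  rows <- list()
  for (a in arrays) {
    stopifnot(identical(a$loci, loci))
    geno_row <- function(g, id, role) {
      rec <- data.frame(population = a$population, family = a$family,
                        individual = id, role = role,
                        stringsAsFactors = FALSE)
      for (j in seq_along(loci)) {
        cc <- locus_cols(j)
        rec[[loci[j]]] <- format_geno_field(g[cc[1L]], g[cc[2L]])
      }
      rec
    }
    if (!is.null(a$mother)) {
      rows[[length(rows) + 1L]] <- geno_row(a$mother,
                                            paste0(a$family, "_M"), "mother")
    }
    for (r in seq_len(nrow(a$offspring))) {
      rows[[length(rows) + 1L]] <- geno_row(a$offspring[r, ],
                                            sprintf("%s_%02d", a$family, r),
                                            "offspring")
    }
  }
  write_tsv(do.call(rbind, rows), path)
}

#' Read a herkogamy measurement table
#'
#' TSV columns: `population`, `plant`, `flower`, `herkogamy` (signed mm,
#' pistil length minus stamen length).
#'
#' @param path file path.
#' @return data.frame of measurements.
#' @export
read_phenotype_table <- function(path) {
  df <- read_tsv_strict(path)
  need_cols(df, c("population", "plant", "flower", "herkogamy"), path)
  h <- suppressWarnings(as.numeric(df$herkogamy))
  bad <- !is.finite(h)
  if (any(bad)) {
    stop(sprintf("row %d: non-finite herkogamy '%s'", which(bad)[1L],
                 df$herkogamy[which(bad)[1L]]), call. = FALSE)
  }
  df$herkogamy <- h
  df
}

#' Read a crossing-experiment fitness table
#'
#' TSV columns: `population`, `mother`, `treatment` (`self`/`outcross`),
#' `fruit`, `seed_set` (proportion of ovules that became seeds, in `[0,1]`),
#' `seed_mass` (per-seed mean mass, mg, > 0).
#'
#' @param path file path.
#' @return data.frame of fitness records.
#' @export
read_fitness_table <- function(path) {
  df <- read_tsv_strict(path)
  need_cols(df, c("population", "mother", "treatment", "fruit",
                  "seed_set", "seed_mass"), path)
  bad_tr <- !df$treatment %in% c("self", "outcross")
  if (any(bad_tr)) {
    stop(sprintf("row %d: treatment must be 'self' or 'outcross'",
                 which(bad_tr)[1L]), call. = FALSE)
  }
  ss <- suppressWarnings(as.numeric(df$seed_set))
  bad <- !is.finite(ss) | ss < 0 | ss > 1
  if (any(bad)) {
    stop(sprintf("row %d: seed_set %s outside [0,1]", which(bad)[1L],
                 df$seed_set[which(bad)[1L]]), call. = FALSE)
  }
  sm <- suppressWarnings(as.numeric(df$seed_mass))
  bad <- !is.finite(sm) | sm <= 0
  if (any(bad)) {
    stop(sprintf("row %d: seed_mass must be > 0", which(bad)[1L]),
         call. = FALSE)
  }
  df$seed_set <- ss
  df$seed_mass <- sm
  df
}

#' Read a per-family mating-system parameter table
#'
#' Reads supplementary-style tables of family-level mating-system summaries
#' (herkogamy, outcrossing rate tm, selfing rate s, primary selfing rate r,
#' equilibrium inbreeding Fe). Headers are sniffed case-insensitively and
#' common synonyms are mapped (`t`, `tm`, `outcrossing rate` -> `tm`, etc.);
#' the separator (tab, comma, or semicolon) is detected from the header line.
#'
#' @param path file path.
#' @return data.frame with standardized columns among: population, family,
#'   herkogamy, tm, s, r, Fe (those found in the file).
#' @export
read_family_params <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", header)) "\t" else if (grepl(";", header)) ";" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"", comment.char = "")
  canon <- function(x) gsub("[^a-z0-9]", "", tolower(x))
  syn <- list(
    population = c("population", "pop", "locality", "site"),
    family     = c("family", "fam", "maternalfamily", "lineage", "id",
                   "maternalplant", "plant", "mother"),
    herkogamy  = c("herkogamy", "herkogamymm", "meanherkogamy",
                   "herkogamyaverage", "hk"),
    tm         = c("tm", "t", "outcrossingrate", "multilocusoutcrossingrate",
                   "outcrossing"),
    s          = c("s", "selfingrate", "selfing", "s1tm"),
    r          = c("r", "primaryselfingrate", "primaryselfing"),
    Fe         = c("fe", "equilibriuminbreeding",
                   "inbreedingcoefficientatequilibrium",
                   "inbreedingatequilibrium", "feq")
  )
  nm <- canon(names(df))
  out <- list()
  for (std in names(syn)) {
    hit <- which(nm %in% syn[[std]])
    if (length(hit)) out[[std]] <- df[[hit[1L]]]
  }
  if (!length(intersect(names(out), c("tm", "s", "r", "Fe")))) {
    stop(path, ": no recognizable mating-system parameter columns",
         call. = FALSE)
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}
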