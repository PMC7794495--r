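#' Write encounter histories in MARK .inp format
#'
#' One record per individual: the 0/1 history string, one frequency column
#' per group (1 in the individual's group, 0 elsewhere), optional individual
#' covariate columns, terminated by a semicolon. Comments identifying the
#' columns are written as `/* ... */` header lines.
#'
#' @param histories Encounter-history data frame (column `history`, plus the
#'   columns named by `group` and `covariates`).
#' @param path Output file path.
#' @param group Optional name of a grouping column; its sorted unique values
#'   define the frequency columns.
#' @param covariates Optional character vector of numeric covariate columns.
#' @return `path`, invisibly.
#' @export
write_inp <- function(histories, path, group = NULL, covariates = NULL) {
  stopifnot("history" %in% names(histories))
  lines <- character(0)
  if (!is.null(group)) {
    lv <- sort(unique(histories[[group]]))
    lines <- c(lines, sprintf("/* groups: %s */", paste(lv, collapse = " ")))
    freq <- sapply(lv, function(g) as.integer(histories[[group]] == g))
    if (is.null(dim(freq))) freq <- matrix(freq, nrow = nrow(histories))
  } else {
    freq <- matrix(1L, nrow(histories), 1)
  }
  if (!is.null(covariates))
    lines <- c(lines, sprintf("/* covariates: %s */",
                              paste(covariates, collapse = " ")))
  body <- histories$history
  for (j in seq_len(ncol(freq))) body <- paste(body, freq[, j])
  for (cv in covariates)
    body <- paste(body, format(histories[[cv]], trim = TRUE))
  writeLines(c(lines, paste0(body, ";")), path)
  invisible(path)
}

#' Read encounter histories from MARK .inp format
#'
#' Parses semicolon-terminated records of history string, frequency columns
#' and optional covariates. Records with a frequency > 1 are expanded to
#' individual rows.
#'
#' @param path Input file.
#' @param group_labels Optional labels for the frequency columns; when
#'   given, a `group` column is reconstructed (one frequency column per
#'   label).
#' @param covariates Optional names for trailing covariate columns.
#' @return Encounter-history data frame with columns `history`, optional
#'   `group`, and any named covariates.
#' @export
read_inp <- function(path, group_labels = NULL, covariates = NULL) {
  raw <- readLines(path, warn = FALSE)
  raw <- gsub("/\\*.*?\\*/", "", raw)
  raw <- trimws(gsub(";", "", raw))
  raw <- raw[nzchar(raw)]
  if (length(raw) == 0) stop("no records in .inp file")
  parts <- strsplit(raw, "[ \t]+")
  n_grp <- if (is.null(group_labels)) 1 else length(group_labels)
  n_cov <- length(covariates)
  rows <- lapply(parts, function(p) {
    if (length(p) < 1 + n_grp + n_cov)
      stop("malformed .inp record: too few fields")
    hist <- p[1]
    freq <- as.numeric(p[2:(1 + n_grp)])
    covs <- if (n_cov > 0)
      as.numeric(p[(2 + n_grp):(1 + n_grp + n_cov)]) else numeric(0)
    g <- if (!is.null(group_labels)) {
      hit <- which(freq != 0)
      if (length(hit) != 1) NA_character_ else group_labels[hit]
    } else NA_character_
    reps <- max(1, max(abs(freq)))
    out <- data.frame(history = rep(hist, reps), stringsAsFactors = FALSE)
    if (!is.null(group_labels)) out$group <- g
    for (k in seq_len(n_cov)) out[[covariates[k]]] <- covs[k]
    out
  })
  do.call(rbind, rows)
}

#' Write genotypes in GenePop format
#'
#' Two-digit allele codes, one population block, `id , 0102 0304 ...` rows.
#' Allele codes are taken from the catalog order of each locus's frequency
#' vector when available, otherwise from the sorted allele names.
#'
#' @param gt An [genotype_table()] object.
#' @param path Output file path.
#' @param title Header line (first line of the file).
#' @return `path`, invisibly.
#' @export
write_genepop <- function(gt, path, title = "owlfam genotypes") {
  stopifnot(inherits(gt, "owl_genotypes"))
  allele_codes <- lapply(seq_along(gt$loci), function(l) {
    al <- if (!is.null(gt$freqs)) names(gt$freqs[[l]])
    else sort(unique(stats::na.omit(c(gt$geno[, l, ]))))
    stats::setNames(sprintf("%02d", seq_along(al)), al)
  })
  lines <- c(title, gt$loci, "Pop")
  for (i in seq_along(gt$ids)) {
    codes <- vapply(seq_along(gt$loci), function(l) {
      a <- gt$geno[i, l, ]
      if (any(is.na(a))) return("0000")
      paste0(allele_codes[[l]][a[1]], allele_codes[[l]][a[2]])
    }, character(1))
    lines <- c(lines, paste0(gt$ids[i], " ,  ", paste(codes, collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read genotypes from GenePop format
#'
#' Accepts 2- or 3-digit allele codes and one or more `Pop` blocks (blocks
#' are concatenated; a `population` attribute records the block of each
#' individual). `00`/`000` codes become missing alleles.
#'
#' @param path Input file.
#' @return An [genotype_table()] object (allele codes as recorded, e.g.
#'   `"01"`).
#' @export
read_genepop <- function(path) {
  raw <- trimws(readLines(path, warn = FALSE))
  raw <- raw[nzchar(raw)]
  if (length(raw) < 3) stop("not a GenePop file: too few lines")
  pop_rows <- grep("^pop$", raw, ignore.case = TRUE)
  if (length(pop_rows) == 0) stop("not a GenePop file: no 'Pop' line")
  header <- raw[2:(pop_rows[1] - 1)]
  loci <- unlist(strsplit(header, "[,][ ]*"), use.names = FALSE)
  loci <- trimws(loci[nzchar(trimws(loci))])
  L <- length(loci)
  ind_lines <- setdiff((pop_rows[1] + 1):length(raw), pop_rows)
  pops <- findInterval(ind_lines, pop_rows)
  ids <- character(0)
  rows <- list()
  for (k in seq_along(ind_lines)) {
    ln <- raw[ind_lines[k]]
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2) stop("malformed GenePop individual line")
    id <- trimws(parts[1])
    codes <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[ \t]+")[[1]]
    if (length(codes) != L)
      stop(sprintf("individual '%s' has %d loci, expected %d",
                   id, length(codes), L))
    digits <- nchar(codes[1]) / 2
    a1 <- substr(codes, 1, digits)
    a2 <- substr(codes, digits + 1, 2 * digits)
    a1[as.integer(a1) == 0] <- NA
    a2[as.integer(a2) == 0] <- NA
    ids <- c(ids, id)
    rows[[k]] <- rbind(a1, a2)
  }
  geno <- array(NA_character_, dim = c(length(ids), L, 2),
                dimnames = list(ids, loci, NULL))
  for (k in seq_along(rows)) {
    geno[k, , 1] <- rows[[k]][1, ]
    geno[k, , 2] <- rows[[k]][2, ]
  }
  gt <- genotype_table(ids = ids, geno = geno)
  attr(gt, "population") <- pops
  gt
}

#' Write the simulator's tabular outputs
#'
#' Plain-CSV writers for nests, breeding events, chicks and dispersal
#' records, with the column sets downstream readers expect.
#'
#' @param x Data frame from the corresponding generator.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @name write_tables
NULL

#' @rdname write_tables
#' @export
write_nests_csv <- function(x, path) {
  utils::write.csv(x[, c("nest_id", "habitat", "x_km", "y_km")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_tables
#' @export
write_events_csv <- function(x, path) {
  utils::write.csv(x[, c("nest_id", "year", "unit_type", "n_extra_adults",
                         "productivity")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tables
#' @export
write_indices_csv <- function(x, path) {
  cols <- intersect(c("nest_id", "year", "S", "P", "P_resid"), names(x))
  utils::write.csv(x[, cols], path, row.names = FALSE)
  invisible(path)
}
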