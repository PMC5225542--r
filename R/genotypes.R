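#' Biallelic SNP genotype matrix
#'
#' Container for DArT-style scored SNP genotypes: a matrix of individuals
#' (rows) by loci (columns) holding scores in the DArT convention
#' (`0` = reference-allele homozygote, `1` = alternate-allele homozygote,
#' `2` = heterozygote, `NA` = missing call), plus a per-locus metadata table
#' carrying the clone identifier and replicate-based repeatability where
#' available.
#'
#' @param scores Integer matrix, individuals x loci, values in
#'   `c(0, 1, 2, NA)`. Must have unique row names (individual ids) and
#'   column names (locus ids).
#' @param loci Optional tibble with one row per locus. Columns `locus`,
#'   and optionally `clone_id` and `repeatability`. Defaults to a bare
#'   table built from the column names.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(scores, loci = NULL) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "integer"
  if (is.null(rownames(scores)) && nrow(scores) > 0) {
    rownames(scores) <- paste0("ind_", seq_len(nrow(scores)))
  }
  if (is.null(colnames(scores)) && ncol(scores) > 0) {
    colnames(scores) <- paste0("locus_", seq_len(ncol(scores)))
  }
  if (anyDuplicated(rownames(scores))) {
    stop("duplicate individual ids: ",
         paste(unique(rownames(scores)[duplicated(rownames(scores))]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(scores))) {
    stop("duplicate locus ids", call. = FALSE)
  }
  bad <- scores[!is.na(scores)]
  if (length(bad) && !all(bad %in% 0:2)) {
    stop("genotype scores must be 0, 1, 2 or NA", call. = FALSE)
  }
  if (is.null(loci)) {
    loci <- tibble::tibble(locus = colnames(scores),
                           clone_id = NA_character_,
                           repeatability = NA_real_)
  } else {
    loci <- tibble::as_tibble(loci)
    stopifnot("locus" %in% names(loci))
    if (!"clone_id" %in% names(loci)) loci$clone_id <- NA_character_
    if (!"repeatability" %in% names(loci)) loci$repeatability <- NA_real_
    if (!identical(loci$locus, colnames(scores))) {
      loci <- loci[match(colnames(scores), loci$locus), ]
      if (anyNA(loci$locus)) stop("loci table does not cover all loci", call. = FALSE)
    }
  }
  structure(list(scores = scores, loci = loci), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d individuals x %d loci; %.1f%% missing\n",
              nrow(x$scores), ncol(x$scores),
              100 * mean(is.na(x$scores))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$scores)

#' Individual and locus ids of a genotype matrix
#' @param G A [geno_matrix()].
#' @return Character vector of ids.
#' @export
individuals <- function(G) rownames(G$scores)

#' @rdname individuals
#' @export
loci <- function(G) colnames(G$scores)

#' Subset a genotype matrix
#'
#' @param G A [geno_matrix()].
#' @param ind,loc Individual / locus selectors (names, indices or logical).
#' @return A [geno_matrix()].
#' @export
geno_subset <- function(G, ind = NULL, loc = NULL) {
  s <- G$scores
  if (!is.null(ind)) s <- s[ind, , drop = FALSE]
  if (!is.null(loc)) s <- s[, loc, drop = FALSE]
  geno_matrix(s, G$loci[match(colnames(s), G$loci$locus), ])
}

# Alternate-allele dosage (0/1/2 copies of the SNP allele); DArT score 1 is
# the alternate homozygote and score 2 the heterozygote.
geno_dosage <- function(G) {
  s <- if (inherits(G, "geno_matrix")) G$scores else G
  d <- s
  d[s == 1L] <- 2L
  d[s == 2L] <- 1L
  d
}

#' Read a genotype table
#'
#' Three dialects are supported. `dart_scored` is a locus-per-row CSV with
#' columns `locus`, `clone_id`, `repeatability` followed by one column per
#' individual; missing calls are written `-`. `plain_csv` is an
#' individual-per-row CSV whose first column is the individual id; missing
#' calls are empty cells. `genepop` reads the two-digit-allele Genepop
#' format produced by [write_genepop()]. All dialects score genotypes
#' 0 = reference homozygote, 1 = alternate homozygote, 2 = heterozygote.
#'
#' @param path Path to the file.
#' @param dialect One of `"dart_scored"`, `"plain_csv"`, `"genepop"`.
#' @return A [geno_matrix()]. For `genepop`, the population assignment read
#'   from the `POP` blocks is attached as attribute `"populations"`.
#' @export
read_genotypes <- function(path, dialect = c("dart_scored", "plain_csv", "genepop")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(dialect,
         dart_scored = read_dart_scored(path),
         plain_csv = read_plain_csv(path),
         genepop = read_genepop(path))
}

parse_scores <- function(x, rows, cols, missing_tokens) {
  x <- trimws(x)
  x[x %in% missing_tokens] <- NA
  ok <- is.na(x) | x %in% c("0", "1", "2")
  if (!all(ok)) {
    i <- which(!ok)[1]
    stop(sprintf("malformed score token '%s' at row '%s', column '%s'",
                 x[i], rows[i], cols[i]), call. = FALSE)
  }
  as.integer(x)
}

read_dart_scored <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  meta_cols <- intersect(c("locus", "clone_id", "repeatability"), names(raw))
  if (!"locus" %in% meta_cols) stop("dart_scored file needs a 'locus' column", call. = FALSE)
  ind <- setdiff(names(raw), meta_cols)
  L <- nrow(raw)
  cells <- as.matrix(raw[, ind, drop = FALSE])
  sc <- parse_scores(as.vector(cells),
                     rows = rep(raw$locus, times = length(ind)),
                     cols = rep(ind, each = L),
                     missing_tokens = c("-", ""))
  scores <- t(matrix(sc, nrow = L, dimnames = list(raw$locus, ind)))
  loci <- tibble::tibble(
    locus = raw$locus,
    clone_id = if ("clone_id" %in% meta_cols) dplyr::na_if(raw$clone_id, "") else NA_character_,
    repeatability = if ("repeatability" %in% meta_cols)
      suppressWarnings(as.numeric(raw$repeatability)) else NA_real_)
  geno_matrix(scores, loci)
}

read_plain_csv <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  ids <- raw[[1]]
  if (anyDuplicated(ids)) stop("duplicate individual ids in ", path, call. = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  sc <- parse_scores(as.vector(m),
                     rows = rep(ids, times = ncol(m)),
                     cols = rep(colnames(m), each = nrow(m)),
                     missing_tokens = c("", "-", "NA"))
  scores <- matrix(sc, nrow = length(ids), dimnames = list(ids, colnames(m)))
  geno_matrix(scores)
}

#' Write a genotype table
#'
#' @inheritParams read_genotypes
#' @param G A [geno_matrix()].
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(G, path, dialect = c("dart_scored", "plain_csv")) {
  dialect <- match.arg(dialect)
  s <- G$scores
  if (dialect == "dart_scored") {
    body <- t(s)
    body[is.na(body)] <- NA
    df <- data.frame(locus = G$loci$locus,
                     clone_id = G$loci$clone_id,
                     repeatability = G$loci$repeatability,
                     check.names = FALSE)
    cells <- matrix(as.character(body), nrow = nrow(body))
    cells[is.na(cells)] <- "-"
    colnames(cells) <- rownames(s)
    utils::write.csv(cbind(df, cells), path, row.names = FALSE, quote = FALSE, na = "")
  } else {
    df <- data.frame(individual = rownames(s), check.names = FALSE)
    cells <- matrix(as.character(s), nrow = nrow(s))
    cells[is.na(cells)] <- ""
    colnames(cells) <- colnames(s)
    utils::write.csv(cbind(df, cells), path, row.names = FALSE, quote = FALSE, na = "")
  }
  invisible(path)
}

#' Write genotypes in Genepop format
#'
#' Biallelic loci are coded as two-digit alleles (`01` reference, `02`
#' alternate), missing calls as `0000`. Populations appear as `POP` blocks
#' in the order of first appearance in the population map.
#'
#' @param G A [geno_matrix()].
#' @param map A population map (see [pop_map()]); every individual in `G`
#'   must be mapped.
#' @param path Output path.
#' @param title Title line for the file.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(G, map, path, title = "pearlscape export") {
  ids <- individuals(G)
  pop <- map$population[match(ids, map$individual)]
  if (anyNA(pop)) {
    stop("unmapped individuals: ",
         paste(utils::head(ids[is.na(pop)], 5), collapse = ", "), call. = FALSE)
  }
  code <- c(`0` = "0101", `1` = "0202", `2` = "0102")
  s <- G$scores
  cells <- matrix("0000", nrow = nrow(s), ncol = ncol(s))
  ok <- !is.na(s)
  cells[ok] <- code[as.character(s[ok])]
  lines <- c(title, colnames(s))
  for (p in unique(map$population[map$individual %in% ids])) {
    sel <- which(pop == p)
    if (!length(sel)) next
    lines <- c(lines, "POP",
               paste0(ids[sel], " ,  ",
                      apply(cells[sel, , drop = FALSE], 1, paste, collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}

read_genepop <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  pop_idx <- which(toupper(trimws(lines)) == "POP")
  if (!length(pop_idx)) stop("no POP records found in ", path, call. = FALSE)
  loc_lines <- lines[2:(pop_idx[1] - 1)]
  loc_names <- trimws(unlist(strsplit(loc_lines, ",")))
  blocks <- split(seq_along(lines)[-seq_len(pop_idx[1])],
                  cumsum(toupper(trimws(lines)) == "POP")[-seq_len(pop_idx[1])])
  ids <- character(); pops <- character(); rows <- list()
  decode <- function(tok, id) {
    out <- match(tok, c("0101", "0202", "0102", "0201", "0000")) - 1L
    if (anyNA(out)) {
      stop(sprintf("malformed score token '%s' at row '%s'",
                   tok[which(is.na(out))[1]], id), call. = FALSE)
    }
    out[out == 3L] <- 2L
    out[out == 4L] <- NA_integer_
    out
  }
  k <- 0L
  for (b in seq_along(blocks)) {
    for (i in blocks[[b]]) {
      ln <- lines[i]
      if (toupper(trimws(ln)) == "POP") next
      parts <- strsplit(ln, ",")[[1]]
      id <- trimws(parts[1])
      toks <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[[:space:]]+")[[1]]
      k <- k + 1L
      ids[k] <- id; pops[k] <- paste0("pop_", b)
      rows[[k]] <- decode(toks, id)
    }
  }
  if (anyDuplicated(ids)) stop("duplicate individual ids in ", path, call. = FALSE)
  scores <- do.call(rbind, rows)
  dimnames(scores) <- list(ids, loc_names)
  out <- geno_matrix(scores)
  attr(out, "populations") <- tibble::tibble(individual = ids, population = pops)
  out
}
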