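#' Construct and validate a trait table
#'
#' A trait table is the long-format container used throughout the package:
#' one row per observation of one trait on one plant, keyed by
#' (genotype, treatment, trial, replicate, trait, week). Treatments are the
#' two irrigation regimes PW (ponded water) and LW (limited water);
#' subspecies is `japonica` or `indica`. Treatment and subspecies tokens are
#' case-insensitive on input and canonicalized.
#'
#' @param df A data frame with columns `genotype`, `subspecies`,
#'   `treatment`, `trial`, `replicate`, `trait`, `week`, `value`.
#' @param provenance Optional free-text provenance note.
#' @return A data frame of class `trait_table`.
#' @export
trait_table <- function(df, provenance = "") {
  required <- c("genotype", "subspecies", "treatment", "trial",
                "replicate", "trait", "week", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("trait table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) stop("trait table must be non-empty", call. = FALSE)

  df <- as.data.frame(df)[required]
  df$treatment <- canonical_token(df$treatment, c("PW", "LW"), "treatment")
  df$subspecies <- canonical_token(df$subspecies, c("japonica", "indica"),
                                   "subspecies")
  df$genotype <- as.character(df$genotype)
  df$trial <- as.character(df$trial)
  df$trait <- as.character(df$trait)

  if (!is.numeric(df$value)) {
    stop("value column must be numeric", call. = FALSE)
  }
  if (any(!is.finite(df$value))) {
    stop("non-finite value(s) at row(s): ",
         paste(utils::head(which(!is.finite(df$value)), 5), collapse = ", "),
         call. = FALSE)
  }
  df$replicate <- as.integer(df$replicate)
  if (any(is.na(df$replicate)) || any(df$replicate < 1L)) {
    stop("replicate must be a positive integer", call. = FALSE)
  }
  df$week <- as.integer(df$week)
  if (any(is.na(df$week)) || any(df$week < 0L)) {
    stop("week must be a non-negative integer", call. = FALSE)
  }

  key <- do.call(paste, c(df[c("genotype", "treatment", "trial",
                               "replicate", "trait", "week")], sep = "\r"))
  if (anyDuplicated(key)) {
    stop("duplicate observation key(s), e.g. row ",
         which(duplicated(key))[1], call. = FALSE)
  }

  rownames(df) <- NULL
  attr(df, "provenance") <- provenance
  class(df) <- c("trait_table", "data.frame")
  df
}

canonical_token <- function(x, levels, what) {
  x <- as.character(x)
  idx <- match(tolower(x), tolower(levels))
  if (anyNA(idx)) {
    bad <- unique(x[is.na(idx)])
    stop("invalid ", what, " token(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(levels, collapse = ", "), ")",
         call. = FALSE)
  }
  levels[idx]
}

#' Read a trait table from delimited text
#'
#' Expects a header row naming the seven key columns plus `value`. Comma is
#' the default delimiter; pass `sep = "\t"` for TSV. Decimal points only.
#'
#' @param path Path to a delimited text file.
#' @param sep Field delimiter.
#' @return A [trait_table()].
#' @export
read_trait_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", comment.char = "#",
                           stringsAsFactors = FALSE, check.names = TRUE)
  required <- c("genotype", "subspecies", "treatment", "trial",
                "replicate", "trait", "week", "value")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  value <- suppressWarnings(as.numeric(raw$value))
  if (anyNA(value)) {
    stop("non-numeric value at data row(s): ",
         paste(utils::head(which(is.na(value)), 5), collapse = ", "),
         call. = FALSE)
  }
  raw$value <- value
  trait_table(raw, provenance = path)
}

#' Write a trait table to delimited text
#'
#' Values are serialized with 17 significant digits so that
#' `read_trait_table(write_trait_table(t))` reproduces `t` exactly.
#'
#' @param table A [trait_table()].
#' @param path Output path.
#' @param sep Field delimiter.
#' @return Invisibly, `path`.
#' @export
write_trait_table <- function(table, path, sep = ",") {
  if (!inherits(table, "trait_table")) table <- trait_table(table)
  out <- as.data.frame(table)
  out$value <- vapply(out$value, function(v) sprintf("%.17g", v), "")
  ok <- tryCatch({
    utils::write.table(out, path, sep = sep, row.names = FALSE,
                       quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("could not write trait table to ", path, ": ",
         conditionMessage(ok), call. = FALSE)
  }
  invisible(path)
}

#' Reshape a trait table to a wide unit x trait mean matrix
#'
#' Helper used by the correlation, PCA and PLS stages: averages replicates
#' (and trials) to one value per unit per trait, where a unit is either a
#' genotype or a genotype-treatment combination.
#'
#' @param table A [trait_table()].
#' @param unit `"genotype_treatment"` (default) or `"genotype"`.
#' @param traits Optional trait subset; defaults to all traits present.
#' @return A numeric matrix with units as rows and traits as columns, with
#'   a `meta` attribute data frame describing the rows.
#' @export
trait_means_matrix <- function(table, unit = c("genotype_treatment", "genotype"),
                               traits = NULL) {
  unit <- match.arg(unit)
  stopifnot(inherits(table, "trait_table"))
  if (is.null(traits)) traits <- sort(unique(table$trait))
  tab <- table[table$trait %in% traits, , drop = FALSE]
  if (unit == "genotype_treatment") {
    id <- paste(tab$genotype, tab$treatment, sep = ":")
  } else {
    id <- tab$genotype
  }
  means <- tapply(tab$value, list(id, factor(tab$trait, levels = traits)),
                  mean)
  mat <- matrix(as.numeric(means), nrow = nrow(means),
                dimnames = dimnames(means))
  meta <- data.frame(unit = rownames(mat), stringsAsFactors = FALSE)
  if (unit == "genotype_treatment") {
    parts <- strsplit(rownames(mat), ":", fixed = TRUE)
    meta$genotype <- vapply(parts, `[`, "", 1L)
    meta$treatment <- vapply(parts, `[`, "", 2L)
  } else {
    meta$genotype <- rownames(mat)
  }
  attr(mat, "meta") <- meta
  mat
}

#' Reshape a trait table to a wide plant x trait matrix
#'
#' One row per individual plant (genotype x treatment x trial x replicate x
#' week), one column per trait; used when an analysis should run at
#' replicate level rather than on genotype means.
#'
#' @inheritParams trait_means_matrix
#' @return A numeric matrix with a `meta` attribute describing the rows.
#' @export
plant_trait_matrix <- function(table, traits = NULL) {
  stopifnot(inherits(table, "trait_table"))
  if (is.null(traits)) traits <- sort(unique(table$trait))
  tab <- table[table$trait %in% traits, , drop = FALSE]
  id <- do.call(paste, c(tab[c("genotype", "treatment", "trial",
                               "replicate", "week")], sep = ":"))
  means <- tapply(tab$value, list(id, factor(tab$trait, levels = traits)),
                  mean)
  mat <- matrix(as.numeric(means), nrow = nrow(means),
                dimnames = dimnames(means))
  parts <- strsplit(rownames(mat), ":", fixed = TRUE)
  meta <- data.frame(
    genotype = vapply(parts, `[`, "", 1L),
    treatment = vapply(parts, `[`, "", 2L),
    trial = vapply(parts, `[`, "", 3L),
    replicate = as.integer(vapply(parts, `[`, "", 4L)),
    week = as.integer(vapply(parts, `[`, "", 5L)),
    stringsAsFactors = FALSE
  )
  attr(mat, "meta") <- meta
  mat
}

#' @export
print.trait_table <- function(x, ...) {
  cat("<trait_table> ", nrow(x), " observations, ",
      length(unique(x$genotype)), " genotypes, ",
      length(unique(x$trait)), " traits\n", sep = "")
  NextMethod()
}
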