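#' Interaction evidence sets
#'
#' An `interaction_set` holds deduplicated miRNA -> target interaction
#' evidence (miRNA-lncRNA and/or miRNA-mRNA) such as would be integrated
#' from validated interaction databases. It is the substrate for the
#' shared-miRNA enrichment stage: the set of miRNAs with any evidence
#' defines the universe of the hypergeometric test.
#'
#' @name interaction_set
#' @keywords internal
NULL

.TARGET_CLASSES <- c("mRNA", "lncRNA")

new_interaction_set <- function(records) {
  stopifnot(is.data.frame(records))
  records <- records[, c("mirna_id", "target_id", "target_class", "source")]
  rownames(records) <- NULL
  structure(list(records = records), class = "interaction_set")
}

#' Build an interaction set from a data frame
#'
#' Validates, trims and deduplicates interaction records. Deduplication is
#' on the (mirna_id, target_id, target_class) triple by exact string match
#' after trimming leading/trailing whitespace; the source label of the first
#' occurrence is kept. Identifier matching is deliberately literal: no case
#' folding and no miRBase-style version harmonization is attempted.
#'
#' @param df data frame with columns `mirna_id`, `target_id`,
#'   `target_class` (one of `"mRNA"`, `"lncRNA"`) and optionally `source`.
#' @return An `interaction_set`.
#' @export
interaction_set <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("mirna_id", "target_id", "target_class")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("interaction data frame lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (!nrow(df)) stop("no usable interaction evidence (zero records)")
  df$mirna_id <- trimws(as.character(df$mirna_id))
  df$target_id <- trimws(as.character(df$target_id))
  df$target_class <- trimws(as.character(df$target_class))
  if (is.null(df$source)) df$source <- NA_character_
  df$source <- as.character(df$source)
  if (any(!nzchar(df$mirna_id)) || any(!nzchar(df$target_id))) {
    stop("empty mirna_id or target_id after trimming")
  }
  bad <- !df$target_class %in% .TARGET_CLASSES
  if (any(bad)) {
    stop("invalid target_class value(s): ",
         paste(unique(df$target_class[bad]), collapse = ", "),
         " (expected mRNA or lncRNA)")
  }
  key <- paste(df$mirna_id, df$target_id, df$target_class, sep = "\r")
  df <- df[!duplicated(key), , drop = FALSE]
  # a (mirna, target) pair must have a single target class
  pair <- paste(df$mirna_id, df$target_id, sep = "\r")
  dup <- pair[duplicated(pair)]
  if (length(dup)) {
    offender <- strsplit(dup[1L], "\r", fixed = TRUE)[[1L]]
    stop("conflicting target_class for pair (", offender[1L], ", ",
         offender[2L], "): annotation inconsistency")
  }
  new_interaction_set(df)
}

#' Load a miRNA-target interaction table
#'
#' Reads a tab-separated evidence file (UTF-8; optional header lines start
#' with `#`) with columns `mirna_id`, `target_id` and optionally
#' `target_class` and `source`. Malformed rows (fewer than two fields or
#' empty identifiers) are skipped with a warning that reports their line
#' numbers and count.
#'
#' @param path path to the evidence file.
#' @param target_class target class (`"mRNA"` or `"lncRNA"`) assigned to
#'   rows that do not carry their own class column; rows with an explicit
#'   class must agree with it.
#' @return An `interaction_set`.
#' @export
load_interactions <- function(path, target_class = c("mRNA", "lncRNA")) {
  target_class <- match.arg(target_class)
  if (!file.exists(path)) stop("interaction file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !startsWith(trimws(lines), "#")
  lineno <- which(keep & nzchar(trimws(lines)))
  if (!length(lineno)) stop("empty interaction file (no usable evidence): ", path)
  fields <- strsplit(lines[lineno], "\t", fixed = TRUE)
  n_col <- lengths(fields)
  get_col <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  mirna <- trimws(get_col(1L))
  target <- trimws(get_col(2L))
  class_col <- trimws(get_col(3L))
  source_col <- get_col(4L)
  malformed <- n_col < 2L | !nzchar(mirna) | is.na(target) | !nzchar(ifelse(is.na(target), "", target))
  cls_given <- !is.na(class_col) & nzchar(class_col)
  mismatch <- cls_given & class_col != target_class & !malformed
  if (any(mismatch)) {
    malformed <- malformed | mismatch
  }
  if (any(malformed)) {
    warning(sum(malformed), " malformed row(s) skipped at line(s): ",
            paste(utils::head(lineno[malformed], 10L), collapse = ", "),
            if (sum(malformed) > 10L) ", ..." else "")
  }
  ok <- !malformed
  if (!any(ok)) stop("empty interaction file (no usable evidence): ", path)
  interaction_set(data.frame(
    mirna_id = mirna[ok],
    target_id = target[ok],
    target_class = target_class,
    source = source_col[ok],
    stringsAsFactors = FALSE
  ))
}

#' Merge interaction sets
#'
#' Takes the union of the records of one or more interaction sets with
#' global deduplication. A (mirna, target) pair recorded with different
#' target classes in different sets is an annotation inconsistency and
#' raises an error naming the pair.
#'
#' @param ... `interaction_set` objects.
#' @return The merged `interaction_set`.
#' @export
merge_interactions <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]]) && !inherits(sets[[1L]], "interaction_set")) {
    sets <- sets[[1L]]
  }
  if (!length(sets)) stop("no interaction sets to merge")
  for (s in sets) stopifnot(inherits(s, "interaction_set"))
  interaction_set(do.call(rbind, lapply(sets, function(s) s$records)))
}

#' @export
merge.interaction_set <- function(x, y, ...) merge_interactions(x, y, ...)

#' @export
print.interaction_set <- function(x, ...) {
  cat("interaction_set:", nrow(x$records), "records,",
      length(mirna_universe(x)), "distinct miRNAs,",
      length(unique(x$records$target_id)), "targets\n")
  tab <- table(x$records$target_class)
  for (cl in names(tab)) cat("  ", cl, ": ", tab[[cl]], " records\n", sep = "")
  invisible(x)
}

#' Number of interaction records
#' @param s an `interaction_set`.
#' @return Integer record count.
#' @export
n_interactions <- function(s) {
  stopifnot(inherits(s, "interaction_set"))
  nrow(s$records)
}

#' The miRNA universe of an interaction set
#'
#' All distinct miRNA identifiers with evidence against any target class.
#' The pooled (not per-class) universe is what the shared-miRNA
#' hypergeometric test conditions on.
#'
#' @param s an `interaction_set`.
#' @return Character vector of miRNA ids, sorted.
#' @export
mirna_universe <- function(s) {
  stopifnot(inherits(s, "interaction_set"))
  sort(unique(s$records$mirna_id))
}

#' miRNAs with evidence against a gene
#' @param s an `interaction_set`.
#' @param gene target gene id.
#' @return Character vector of miRNA ids, sorted.
#' @export
mirnas_of <- function(s, gene) {
  stopifnot(inherits(s, "interaction_set"), length(gene) == 1L)
  if (!gene %in% s$records$target_id) stop("unknown target gene: ", gene)
  sort(unique(s$records$mirna_id[s$records$target_id == gene]))
}

#' Targets of a miRNA
#' @param s an `interaction_set`.
#' @param mirna miRNA id.
#' @param target_class optional class filter (`"mRNA"` or `"lncRNA"`).
#' @return Character vector of target ids, sorted.
#' @export
targets_of <- function(s, mirna, target_class = NULL) {
  stopifnot(inherits(s, "interaction_set"), length(mirna) == 1L)
  if (!mirna %in% s$records$mirna_id) stop("unknown miRNA: ", mirna)
  rec <- s$records[s$records$mirna_id == mirna, , drop = FALSE]
  if (!is.null(target_class)) rec <- rec[rec$target_class == target_class, , drop = FALSE]
  sort(unique(rec$target_id))
}

#' Shared miRNAs of a lncRNA-mRNA pair
#'
#' The intersection of the miRNA evidence sets of the two genes; its size
#' is the k of the sharing enrichment test.
#'
#' @param s an `interaction_set`.
#' @param lnc lncRNA id (must be present as a target in `s`).
#' @param mrna mRNA id (must be present as a target in `s`).
#' @return Character vector of shared miRNA ids, sorted.
#' @export
shared_mirnas <- function(s, lnc, mrna) {
  stopifnot(inherits(s, "interaction_set"))
  targets <- unique(s$records$target_id)
  if (!lnc %in% targets) stop("lncRNA not present as a target: ", lnc)
  if (!mrna %in% targets) stop("mRNA not present as a target: ", mrna)
  intersect(mirnas_of(s, lnc), mirnas_of(s, mrna))
}

#' Write an interaction set
#'
#' Emits the tab-separated evidence dialect (columns mirna_id, target_id,
#' target_class, source) deterministically sorted by (mirna_id, target_id).
#'
#' @param s an `interaction_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(s, path) {
  stopifnot(inherits(s, "interaction_set"))
  rec <- s$records
  rec <- rec[order(rec$mirna_id, rec$target_id, method = "radix"), , drop = FALSE]
  rec$source[is.na(rec$source)] <- ""
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("#mirna_id\ttarget_id\ttarget_class\tsource", con)
  writeLines(paste(rec$mirna_id, rec$target_id, rec$target_class, rec$source,
                   sep = "\t"), con)
  invisible(path)
}
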