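#' Tissue-specificity class of a gene expression profile
#'
#' Classifies a per-tissue pTPM profile into one of five classes, following
#' Human Protein Atlas conventions, evaluated in this precedence order:
#' `not-expressed` (all tissues below `min_expr`), `tissue-enriched` (one
#' tissue at least `fold` times every other tissue and above `min_expr`),
#' `group-enriched` (a group of 2..`group_max` tissues, each above
#' `min_expr` and at least `fold` times every outside tissue),
#' `tissue-enhanced` (some tissue above `min_expr` and at least `fold`
#' times the mean of all other tissues), else `low-tissue-specificity`.
#'
#' @param expression named numeric vector of pTPM values, one per tissue
#'   (at least 2 tissues).
#' @param fold fold-change threshold (> 1, default 5).
#' @param min_expr minimum expression in pTPM (default 1).
#' @param group_max maximum group size for group enrichment (default 7).
#' @return A list with `class` (one of the five labels) and
#'   `enriched_tissues` (character vector, possibly empty).
#' @export
classify_specificity <- function(expression, fold = 5, min_expr = 1,
                                 group_max = 7) {
  if (!is.numeric(expression) || any(!is.finite(expression)) ||
      any(expression < 0)) {
    stop("expression must be finite, non-negative pTPM values",
         call. = FALSE)
  }
  if (length(expression) < 2L) {
    stop("cannot classify a single-tissue record: fold comparisons ",
         "are undefined", call. = FALSE)
  }
  if (fold <= 1) stop("fold must be > 1", call. = FALSE)
  if (is.null(names(expression))) {
    names(expression) <- paste0("tissue", seq_along(expression))
  }
  if (all(expression < min_expr)) {
    return(list(class = "not-expressed", enriched_tissues = character(0)))
  }
  ord <- order(expression, decreasing = TRUE)
  sorted <- expression[ord]
  if (sorted[1] >= min_expr && sorted[1] >= fold * sorted[2]) {
    return(list(class = "tissue-enriched",
                enriched_tissues = names(sorted)[1]))
  }
  for (g in 2:min(group_max, length(sorted) - 1L)) {
    outside_max <- sorted[g + 1L]
    if (all(sorted[seq_len(g)] >= min_expr) &&
        sorted[g] >= fold * outside_max) {
      return(list(class = "group-enriched",
                  enriched_tissues = names(sorted)[seq_len(g)]))
    }
  }
  for (i in seq_along(sorted)) {
    if (sorted[i] >= min_expr &&
        sorted[i] >= fold * mean(sorted[-i])) {
      return(list(class = "tissue-enhanced",
                  enriched_tissues = names(sorted)[i]))
    }
  }
  list(class = "low-tissue-specificity", enriched_tissues = character(0))
}

#' Annotate a screen result with expression and predictor evidence
#'
#' Left-joins tissue-specificity classes (computed per gene from a wide
#' pTPM table) and per-peptide predicted binding/immunogenicity values onto
#' a screen result. Rows without annotations are retained with `NA`
#' markers, never dropped. Duplicate keys in an annotation table are an
#' error.
#'
#' @param result a `screen_result`.
#' @param expression optional tibble: column `gene` plus one numeric pTPM
#'   column per tissue.
#' @param binding optional tibble with columns `peptide`, `ic50_nM`,
#'   `immunogenicity` (optionally `allele`).
#' @param ... passed to [classify_specificity()].
#' @return The result with added columns `specificity_class`,
#'   `enriched_tissues`, `ic50_nM`, `immunogenicity`.
#' @export
annotate_screen <- function(result, expression = NULL, binding = NULL, ...) {
  out <- result
  att <- attributes(result)
  if (!is.null(expression)) {
    stopifnot("gene" %in% names(expression))
    if (anyDuplicated(expression$gene)) {
      stop("duplicate gene keys in expression table", call. = FALSE)
    }
    tissues <- setdiff(names(expression), "gene")
    cls <- lapply(seq_len(nrow(expression)), function(i) {
      classify_specificity(
        setNames(as.numeric(expression[i, tissues]), tissues), ...)
    })
    expr_ann <- tibble(
      gene = expression$gene,
      specificity_class = vapply(cls, `[[`, character(1), "class"),
      enriched_tissues = vapply(cls, function(x) {
        paste(x$enriched_tissues, collapse = "|")
      }, character(1))
    )
    out <- left_join(out, expr_ann, by = "gene")
  } else {
    out$specificity_class <- NA_character_
    out$enriched_tissues <- NA_character_
  }
  if (!is.null(binding)) {
    stopifnot(all(c("peptide", "ic50_nM", "immunogenicity")
                  %in% names(binding)))
    if ("allele" %in% names(binding) && !is.null(att$allele)) {
      binding <- binding[normalize_hla(binding$allele) ==
                           att$allele, , drop = FALSE]
    }
    if (anyDuplicated(binding$peptide)) {
      stop("duplicate (peptide, allele) keys in binding table",
           call. = FALSE)
    }
    out$ic50_nM <- NULL; out$immunogenicity <- NULL
    out <- left_join(
      out, binding[, c("peptide", "ic50_nM", "immunogenicity")],
      by = "peptide")
  } else {
    if (!"ic50_nM" %in% names(out)) out$ic50_nM <- NA_real_
    if (!"immunogenicity" %in% names(out)) out$immunogenicity <- NA_real_
  }
  keep <- att[setdiff(names(att), c("names", "row.names", "class"))]
  for (nm in names(keep)) attr(out, nm) <- keep[[nm]]
  class(out) <- att$class
  out
}

#' Flag high-risk off-target candidates
#'
#' A candidate is a strong binder when its predicted IC50 is at most
#' `ic50_cut` (inclusive, default 50 nM), immunogenic when its predicted
#' immunogenicity score strictly exceeds `imm_cut` (default 0.65), and
#' high-risk when both hold.
#'
#' @param annotated an annotated `screen_result` (or any data frame with
#'   `ic50_nM` and `immunogenicity` columns).
#' @param ic50_cut inclusive IC50 cut in nM (> 0).
#' @param imm_cut exclusive immunogenicity cut (> 0).
#' @return The input with added logical columns `strong_binder`,
#'   `immunogenic`, `high_risk` (`NA` where evidence is missing).
#' @export
prioritize <- function(annotated, ic50_cut = 50, imm_cut = 0.65) {
  stopifnot(ic50_cut > 0, imm_cut > 0)
  annotated$strong_binder <- annotated$ic50_nM <= ic50_cut
  annotated$immunogenic <- annotated$immunogenicity > imm_cut
  annotated$high_risk <- annotated$strong_binder & annotated$immunogenic
  annotated
}
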