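#' Percentile rank of a screening position
#'
#' `(1 - rank/N) * 100`: rank 27 out of 36,000 maps to the 99.925th
#' percentile.
#'
#' @param rank 1-based rank(s).
#' @param N universe size.
#' @return Percentage in `[0, 100)`.
#' @export
percentile_rank <- function(rank, N) {
  if (any(rank < 1L) || any(rank > N)) {
    stop("rank must satisfy 1 <= rank <= N", call. = FALSE)
  }
  (1 - rank / N) * 100
}

#' Screen an immunopeptidome for candidates related to a query peptide
#'
#' Scores every database peptide of one HLA allele against the query with
#' the relatedness score, ranks ascending (low RdS = most similar), and
#' attaches percentile ranks and, when a null distribution is supplied,
#' lower-tail p-values. Ties are broken by peptide lexicographic order so
#' ranks are reproducible. The query is not removed from the universe if
#' present: self and paralog hits are legitimate results.
#'
#' @param query a 9-mer peptide sequence.
#' @param db a `peptide_db` (or character vector of 9-mers, treated as a
#'   single-allele universe).
#' @param allele HLA allele restricting the universe; may be omitted when
#'   the database holds a single allele.
#' @param matrix a `property_matrix`.
#' @param weights a [weight_vector()] or `contact_map`; default uniform
#'   (peptide-centered protocol).
#' @param null optional `null_distribution` for p-values.
#' @return A `screen_result` tibble with columns `peptide`, `gene`,
#'   `source`, `rds`, `rank`, `percentile_rank` and (with a null)
#'   `p_value`, sorted by ascending `rds`; attributes `query`, `allele`,
#'   `weight_label`, `matrix_id`, `null`, `universe_size`.
#' @export
cross_screen <- function(query, db, allele = NULL,
                         matrix = default_property_matrix(),
                         weights = NULL, null = NULL) {
  query <- validate_peptides(query)
  stopifnot(length(query) == 1L)
  if (inherits(weights, "contact_map")) weights <- weights$weights
  if (is.null(weights)) weights <- uniform_weights()
  if (is.character(db)) {
    db <- as_peptide_db(tibble(peptide = db,
                               allele = allele %||% "HLA-A*01:01"))
  }
  if (is.null(allele)) {
    alleles <- unique(db$allele)
    if (length(alleles) != 1L) {
      stop("database holds ", length(alleles),
           " alleles; specify `allele`", call. = FALSE)
    }
    allele <- alleles
  }
  universe <- subset_allele(db, allele)
  rds <- rds_against(query, universe$peptide, matrix, weights)
  ord <- order(rds, universe$peptide)
  out <- tibble(
    peptide = universe$peptide[ord],
    gene = universe$gene[ord],
    source = universe$source[ord],
    rds = rds[ord],
    rank = seq_along(ord),
    percentile_rank = percentile_rank(seq_along(ord), length(ord))
  )
  if (!is.null(null)) out$p_value <- rds_p_value(out$rds, null)
  structure(
    out,
    query = query, allele = normalize_hla(allele),
    weight_label = attr(weights, "label"), matrix_id = matrix$matrix_id,
    null = null, universe_size = nrow(out),
    class = c("screen_result", class(out))
  )
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result> query ", attr(x, "query"), " vs ",
      attr(x, "universe_size"), " peptides (", attr(x, "allele"),
      "), weights: ", attr(x, "weight_label"), "\n", sep = "")
  NextMethod()
}

#' Rank of a target peptide within a screen result
#'
#' @param target peptide sequence to look up (exact match).
#' @param result a `screen_result`.
#' @return The 1-based rank, or `NA_integer_` if the target is absent.
#' @export
rank_of <- function(target, result) {
  i <- match(toupper(target), result$peptide)
  if (is.na(i)) NA_integer_ else result$rank[i]
}

#' Screen several queries and/or alleles in one call
#'
#' @param queries character vector of 9-mer queries.
#' @param db a `peptide_db`.
#' @param alleles allele per query (recycled if length 1).
#' @param ... passed on to [cross_screen()].
#' @return A named list of `screen_result`s ("query@allele").
#' @export
cross_screen_batch <- function(queries, db, alleles, ...) {
  queries <- validate_peptides(queries)
  if (length(alleles) == 1L) alleles <- rep(alleles, length(queries))
  stopifnot(length(alleles) == length(queries))
  out <- Map(function(q, al) cross_screen(q, db, allele = al, ...),
             queries, alleles)
  names(out) <- paste0(queries, "@", normalize_hla(alleles))
  out
}
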