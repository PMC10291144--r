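#' Per-position residue frequencies of the top-scoring candidates
#'
#' Tallies residue usage at each peptide position over the `k` best-ranked
#' candidates of a screen; `conservation` is the per-position maximum
#' frequency. TCR-centered weighting typically sharpens conservation at
#' hotspot and anchor positions.
#'
#' @param result a `screen_result`.
#' @param k number of top candidates (1 <= k <= universe size).
#' @return An object of class `substitution_profile`: list with
#'   `frequencies` (20 x 9 matrix, each column summing to 1),
#'   `conservation` (length-9 vector), and `k`.
#' @export
substitution_profile <- function(result, k) {
  if (!is.numeric(k) || k < 1) stop("k must be >= 1", call. = FALSE)
  if (k > nrow(result)) {
    stop("k exceeds the universe size (", nrow(result), ")", call. = FALSE)
  }
  top <- result$peptide[seq_len(k)]
  chars <- matrix(unlist(strsplit(top, ""), use.names = FALSE),
                  nrow = k, ncol = 9, byrow = TRUE)
  freq <- vapply(seq_len(9L), function(p) {
    tab <- table(factor(chars[, p], levels = AA_ALPHABET))
    as.numeric(tab) / k
  }, numeric(20))
  dimnames(freq) <- list(AA_ALPHABET, paste0("P", 1:9))
  structure(
    list(frequencies = freq, conservation = apply(freq, 2, max), k = k),
    class = "substitution_profile"
  )
}

#' @export
print.substitution_profile <- function(x, ...) {
  cat("<substitution_profile> top", x$k, "candidates\n  conservation:",
      paste(format(round(x$conservation, 2)), collapse = " "), "\n")
  invisible(x)
}

#' Compare screening protocols on shared targets
#'
#' For screens of the same universe under different weighting protocols
#' (e.g. peptide-centered vs contact-map weighted), reports the rank of
#' each target under each protocol, the pairwise and total top-`k` overlap
#' sizes, and the fraction of targets recovered in the top `k` per
#' protocol.
#'
#' @param results named list of `screen_result`s over the same universe.
#' @param targets character vector of validated target peptides.
#' @param k top-list size (default 50).
#' @return A list with `ranks` (tibble target x protocol), `top_overlap`
#'   (named counts for each protocol pair and the full intersection), and
#'   `top_fraction` (per-protocol fraction of targets in the top `k`).
#' @export
protocol_comparison <- function(results, targets = character(0), k = 50) {
  stopifnot(is.list(results), length(results) >= 1)
  if (is.null(names(results)) || any(!nzchar(names(results)))) {
    names(results) <- paste0("protocol", seq_along(results))
  }
  universes <- lapply(results, function(r) sort(r$peptide))
  if (length(results) > 1 &&
      !all(vapply(universes[-1], identical, logical(1), universes[[1]]))) {
    stop("screen results cover different universes", call. = FALSE)
  }
  k <- min(k, nrow(results[[1]]))
  ranks <- tibble(target = targets)
  for (nm in names(results)) {
    ranks[[nm]] <- vapply(targets, rank_of, integer(1),
                          result = results[[nm]])
  }
  tops <- lapply(results, function(r) r$peptide[seq_len(k)])
  overlap <- c()
  nms <- names(results)
  if (length(nms) > 1) {
    for (i in seq_along(nms)) {
      for (j in seq_along(nms)) {
        if (i < j) {
          overlap[paste(nms[i], nms[j], sep = "&")] <-
            length(intersect(tops[[i]], tops[[j]]))
        }
      }
    }
  }
  overlap["all"] <- length(Reduce(intersect, tops))
  top_fraction <- vapply(tops, function(t) {
    if (length(targets) == 0) NA_real_ else mean(targets %in% t)
  }, numeric(1))
  list(ranks = ranks, top_overlap = overlap, top_fraction = top_fraction,
       k = k)
}
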