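#' Validate 9-mer peptide sequences
#'
#' Sequences are case-normalized to uppercase and must be 9 residues long
#' over the 20 canonical one-letter amino acids. Violations are hard errors:
#' class I HLA screening in this package is restricted to 9-mers.
#'
#' @param x character vector of peptide sequences.
#' @return The validated, uppercased character vector.
#' @export
validate_peptides <- function(x) {
  if (!is.character(x) || length(x) == 0) {
    stop("peptides must be a non-empty character vector", call. = FALSE)
  }
  x <- toupper(x)
  len <- nchar(x)
  if (any(len != 9L)) {
    bad <- which(len != 9L)[1]
    stop("peptide '", x[bad], "' has length ", len[bad],
         "; only 9-mers are supported", call. = FALSE)
  }
  ok <- grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"), x)
  if (!all(ok)) {
    bad <- x[!ok][1]
    pos <- which(!strsplit(bad, "")[[1]] %in% AA_ALPHABET)[1]
    stop("peptide '", bad, "' contains non-canonical residue '",
         substr(bad, pos, pos), "' at position ", pos, call. = FALSE)
  }
  x
}

#' Per-position penalty weights
#'
#' A weight vector assigns a positive penalty to each peptide position;
#' positions with larger weights contribute more to the relatedness score,
#' encoding TCR recognition hotspots.
#'
#' @param w numeric vector of positive weights, one per position.
#' @param label short name, e.g. "uniform", "CM-crystal".
#' @return An object of class `weight_vector`.
#' @export
weight_vector <- function(w, label = "custom") {
  if (!is.numeric(w) || any(!is.finite(w)) || any(w <= 0)) {
    stop("weights must be finite and > 0 at every position", call. = FALSE)
  }
  structure(as.numeric(w), label = label, class = "weight_vector")
}

#' @rdname weight_vector
#' @param L peptide length.
#' @export
uniform_weights <- function(L = 9) weight_vector(rep(1, L), "uniform")

#' @export
print.weight_vector <- function(x, ...) {
  cat("<weight_vector> ", attr(x, "label"), ": ",
      paste(format(unclass(x)), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Encode a peptide as a biochemical profile
#'
#' A biochemical profile is the L x K matrix whose row i is the descriptor
#' coordinates of the residue at position i — a pure lookup into the
#' property matrix, with no additional scaling.
#'
#' @param peptide a 9-mer sequence.
#' @param matrix a `property_matrix` (default: [default_property_matrix()]).
#' @return A `biochemical_profile`: numeric L x K matrix with attributes
#'   `peptide` and `matrix_id`.
#' @export
encode_peptide <- function(peptide, matrix = default_property_matrix()) {
  stopifnot(inherits(matrix, "property_matrix"))
  peptide <- validate_peptides(peptide)
  stopifnot(length(peptide) == 1L)
  residues <- strsplit(peptide, "")[[1]]
  prof <- matrix$coords[residues, , drop = FALSE]
  rownames(prof) <- paste0("P", seq_along(residues), ".", residues)
  structure(prof, peptide = peptide, matrix_id = matrix$matrix_id,
            class = c("biochemical_profile", "matrix", "array"))
}

#' Relatedness score between two biochemical profiles
#'
#' The relatedness score (RdS) is the length-normalized, position-weighted
#' squared Euclidean distance between two biochemical profiles:
#' \deqn{RdS = \frac{1}{L}\sum_{i=1}^{L} w_i \sum_{k=1}^{K}
#'   (a_{ik} - b_{ik})^2}
#' Low values mean biochemically similar peptides (stronger cross-reactivity
#' candidates); identical sequences score exactly 0. The squared form and
#' the absolute scale are fixed by the calibration step (see
#' [calibrate_rds_scale()] and the package vignette).
#'
#' @param a,b `biochemical_profile`s sharing length and descriptor matrix,
#'   or 9-mer sequences (encoded with `matrix`).
#' @param weights a [weight_vector()]; default uniform (peptide-centered
#'   protocol).
#' @param matrix property matrix used when `a`/`b` are sequences.
#' @return A non-negative scalar.
#' @export
relatedness <- function(a, b, weights = NULL,
                        matrix = default_property_matrix()) {
  if (is.character(a)) a <- encode_peptide(a, matrix)
  if (is.character(b)) b <- encode_peptide(b, matrix)
  stopifnot(inherits(a, "biochemical_profile"),
            inherits(b, "biochemical_profile"))
  if (!identical(attr(a, "matrix_id"), attr(b, "matrix_id"))) {
    stop("profiles were encoded with different property matrices (",
         attr(a, "matrix_id"), " vs ", attr(b, "matrix_id"), ")",
         call. = FALSE)
  }
  if (!identical(dim(a), dim(b))) {
    stop("profiles have incompatible dimensions", call. = FALSE)
  }
  L <- nrow(a)
  if (is.null(weights)) weights <- uniform_weights(L)
  if (length(weights) != L) {
    stop("weight vector length ", length(weights),
         " does not match peptide length ", L, call. = FALSE)
  }
  d2 <- rowSums((unclass(a) - unclass(b))^2)
  sum(as.numeric(weights) * d2) / L
}

# Vectorized screening core: RdS of one query against many candidates via a
# 20x20 per-residue squared-distance lookup. Must agree with relatedness()
# applied pair by pair (asserted by the oracle-equivalence tests).
rds_against <- function(query, candidates, matrix, weights) {
  pd2 <- as.matrix(dist(matrix$coords))^2
  qi <- match(strsplit(validate_peptides(query), "")[[1]], AA_ALPHABET)
  cm <- matrix(match(unlist(strsplit(candidates, ""), use.names = FALSE),
                     AA_ALPHABET),
               nrow = length(candidates), ncol = 9L, byrow = TRUE)
  w <- as.numeric(weights)
  acc <- numeric(length(candidates))
  for (i in seq_len(9L)) {
    acc <- acc + w[i] * pd2[cbind(qi[i], cm[, i])]
  }
  acc / 9
}

#' Ungapped substitution-matrix score (alignment-based baseline)
#'
#' Position-wise sum of substitution values between two equal-length
#' peptides under a standard NCBI substitution matrix (packaged with
#' Biostrings). Higher means more similar; used only as a ranking baseline
#' against the relatedness score.
#'
#' @param a,b peptide sequences of equal length.
#' @param matrix_name e.g. "BLOSUM62", "BLOSUM100".
#' @return Integer score.
#' @export
blosum_score <- function(a, b, matrix_name = "BLOSUM62") {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) {
    stop("sequences must have equal length for ungapped scoring",
         call. = FALSE)
  }
  mat <- tryCatch(
    {
      env <- new.env(parent = emptyenv())
      suppressMessages(
        utils::data(list = matrix_name, package = "Biostrings", envir = env))
      env[[matrix_name]]
    },
    warning = function(w) NULL, error = function(e) NULL
  )
  if (is.null(mat) || !is.matrix(mat)) {
    stop("unknown substitution matrix '", matrix_name, "'", call. = FALSE)
  }
  ra <- strsplit(a, "")[[1]]
  rb <- strsplit(b, "")[[1]]
  sum(mat[cbind(ra, rb)])
}
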