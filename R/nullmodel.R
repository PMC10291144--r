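#' Monte-Carlo sample of relatedness scores from random peptide pairs
#'
#' Draws `n` peptide pairs from the pooled (allele-agnostic) database —
#' both ends sampled independently and uniformly with replacement — and
#' scores each pair with the relatedness score. This emulates the
#' background of unrelated self-peptide pairs against which screening hits
#' are judged; at full scale the reference analysis used 5 million pairs
#' across a wide range of class I alleles.
#'
#' @param db a `peptide_db` (or character vector of 9-mers).
#' @param n number of pairs (>= 2).
#' @param seed integer seed; identical (db, n, seed) reproduce the sample.
#' @param matrix a `property_matrix`.
#' @param weights a [weight_vector()]; default uniform.
#' @param stratify_by_allele if TRUE, both peptides of a pair are drawn from
#'   the same (uniformly chosen) allele instead of the pooled set.
#' @return Numeric vector of `n` relatedness scores, with attribute `seed`.
#' @export
sample_rds_pairs <- function(db, n, seed = 1,
                             matrix = default_property_matrix(),
                             weights = NULL, stratify_by_allele = FALSE) {
  peptides <- if (is.character(db)) db else db$peptide
  alleles <- if (is.character(db)) NULL else db$allele
  if (length(peptides) < 1L) stop("empty database", call. = FALSE)
  if (!is.numeric(n) || n < 2) stop("need n >= 2 pairs", call. = FALSE)
  n <- as.integer(n)
  if (is.null(weights)) weights <- uniform_weights()
  pd2 <- as.matrix(dist(matrix$coords))^2
  enc <- matrix(match(unlist(strsplit(peptides, ""), use.names = FALSE),
                      AA_ALPHABET),
                nrow = length(peptides), ncol = 9L, byrow = TRUE)
  w <- as.numeric(weights)
  local_seed(seed, {
    if (stratify_by_allele && !is.null(alleles)) {
      pick <- sample(unique(alleles), n, replace = TRUE)
      idx <- split(seq_len(n), pick)
      i <- j <- integer(n)
      for (al in names(idx)) {
        pool <- which(alleles == al)
        i[idx[[al]]] <- sample(pool, length(idx[[al]]), replace = TRUE)
        j[idx[[al]]] <- sample(pool, length(idx[[al]]), replace = TRUE)
      }
    } else {
      i <- sample.int(length(peptides), n, replace = TRUE)
      j <- sample.int(length(peptides), n, replace = TRUE)
    }
    acc <- numeric(n)
    for (p in seq_len(9L)) {
      acc <- acc + w[p] * pd2[cbind(enc[i, p], enc[j, p])]
    }
    structure(acc / 9, seed = seed)
  })
}

#' Gaussian null distribution of relatedness scores
#'
#' `fit_null()` fits by moments (sample mean and standard deviation) and
#' records a Shapiro-Wilk normality diagnostic computed on a fixed-seed
#' subsample of at most 5,000 scores (the exact test is not defined for
#' millions of points); the diagnostic is informational and never blocks.
#' `null_distribution()` builds the object directly from known parameters,
#' e.g. the published full-scale fit (mu 32.77, sigma 6.05).
#'
#' @param scores numeric vector of relatedness scores (>= 2 finite values).
#' @return An object of class `null_distribution` with fields `mu`, `sigma`,
#'   `n_pairs`, `shapiro_W`, `shapiro_p`, `seed`, `db_id`.
#' @export
fit_null <- function(scores) {
  scores <- scores[is.finite(scores)]
  if (length(scores) < 2L) {
    stop("need at least 2 finite scores", call. = FALSE)
  }
  s <- sd(scores)
  if (s == 0) {
    stop("degenerate score distribution: zero variance", call. = FALSE)
  }
  sub <- if (length(scores) > 5000L) {
    local_seed(1L, sample(scores, 5000L))
  } else scores
  sw <- tryCatch(shapiro.test(sub),
                 error = function(e) list(statistic = NA_real_,
                                          p.value = NA_real_))
  null_distribution(
    mu = mean(scores), sigma = s, n_pairs = length(scores),
    shapiro_W = unname(sw$statistic), shapiro_p = sw$p.value,
    seed = attr(scores, "seed") %||% NA_integer_
  )
}

#' @rdname fit_null
#' @param mu,sigma Gaussian parameters (RdS units); `sigma` > 0.
#' @param n_pairs number of pairs behind the fit.
#' @param shapiro_W,shapiro_p normality diagnostic (optional).
#' @param seed,db_id provenance (optional).
#' @export
null_distribution <- function(mu, sigma, n_pairs = 2L,
                              shapiro_W = NA_real_, shapiro_p = NA_real_,
                              seed = NA_integer_, db_id = NA_character_) {
  if (!is.finite(mu)) stop("mu must be finite", call. = FALSE)
  if (!is.finite(sigma) || sigma <= 0) {
    stop("sigma must be a positive real", call. = FALSE)
  }
  if (n_pairs < 2) stop("n_pairs must be >= 2", call. = FALSE)
  structure(
    list(mu = mu, sigma = sigma, n_pairs = as.integer(n_pairs),
         shapiro_W = shapiro_W, shapiro_p = shapiro_p,
         seed = seed, db_id = db_id),
    class = "null_distribution"
  )
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("<null_distribution> Normal(mu = ", format(x$mu, digits = 6),
      ", sigma = ", format(x$sigma, digits = 6), "), n_pairs = ",
      x$n_pairs, "\n", sep = "")
  if (is.finite(x$shapiro_W)) {
    cat("  Shapiro-Wilk (<=5000 subsample): W = ",
        format(x$shapiro_W, digits = 4), ", p = ",
        format(x$shapiro_p, digits = 3), "\n", sep = "")
  }
  invisible(x)
}

#' Lower-tail p-value of a relatedness score
#'
#' The probability that a random unrelated peptide pair scores at most as
#' low as `score` under the Gaussian null: the lower-tail normal CDF
#' \eqn{\Phi((score - \mu)/\sigma)}. Monotone non-decreasing in `score`.
#'
#' @param score relatedness score(s).
#' @param null a `null_distribution`.
#' @return Probabilities in (0, 1), vectorized over `score`.
#' @export
rds_p_value <- function(score, null) {
  stopifnot(inherits(null, "null_distribution"))
  pnorm(score, mean = null$mu, sd = null$sigma)
}

#' Classify a score against the significance threshold
#'
#' Significant iff the lower-tail p-value is at most `alpha`; the standard
#' screening threshold is p <= 0.01.
#'
#' @param score relatedness score(s).
#' @param null a `null_distribution`.
#' @param alpha significance level in (0, 1).
#' @return Character vector, "significant" or "not-significant".
#' @export
classify_significance <- function(score, null, alpha = 0.01) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  ifelse(rds_p_value(score, null) <= alpha, "significant", "not-significant")
}

#' Binned summary of the null sample
#'
#' Divides relatedness scores into contiguous left-closed bins of width
#' `width` starting at 0 (labels "0-2", "2-4", ...), reporting the fraction
#' of simulated pairs, the count of validated cases, and the mean p-value
#' per bin. The low-score bins are where experimentally validated
#' cross-reactive pairs concentrate.
#'
#' @param scores numeric relatedness scores from the Monte-Carlo sample.
#' @param null a `null_distribution` used for per-bin mean p-values.
#' @param validated optional numeric scores of validated cross-reactive
#'   pairs to count per bin.
#' @param width bin width (default 2).
#' @return A tibble with columns `bin`, `lower`, `upper`, `n`, `fraction`,
#'   `n_validated`, `mean_p_value`; fractions sum to 1.
#' @export
bin_summary <- function(scores, null, validated = numeric(0), width = 2) {
  stopifnot(length(scores) > 0, width > 0)
  top <- max(scores, validated, width)
  breaks <- seq(0, ceiling(top / width) * width, by = width)
  idx <- findInterval(scores, breaks, rightmost.closed = FALSE)
  vidx <- findInterval(validated, breaks, rightmost.closed = FALSE)
  nb <- length(breaks) - 1L
  n <- tabulate(idx, nbins = nb)
  nv <- tabulate(vidx, nbins = nb)
  meanp <- vapply(seq_len(nb), function(b) {
    if (n[b] == 0) NA_real_ else mean(rds_p_value(scores[idx == b], null))
  }, numeric(1))
  tibble(
    bin = paste0(breaks[-length(breaks)], "-", breaks[-1]),
    lower = breaks[-length(breaks)],
    upper = breaks[-1],
    n = n,
    fraction = n / length(scores),
    n_validated = nv,
    mean_p_value = meanp
  )
}

#' Serialize / load a null distribution as JSON
#'
#' Small versioned JSON artifact so screens are reproducible without
#' re-simulation.
#'
#' @param null a `null_distribution`.
#' @param path file path.
#' @return `write_null_json` returns `path` invisibly; `read_null_json`
#'   returns a `null_distribution`.
#' @export
write_null_json <- function(null, path) {
  stopifnot(inherits(null, "null_distribution"))
  jsonlite::write_json(
    c(list(format = "xreact-null/1"), unclass(null)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_null_json
#' @export
read_null_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  null_distribution(
    mu = x$mu, sigma = x$sigma, n_pairs = x$n_pairs,
    shapiro_W = x$shapiro_W %||% NA_real_,
    shapiro_p = x$shapiro_p %||% NA_real_,
    seed = x$seed %||% NA_integer_, db_id = x$db_id %||% NA_character_
  )
}
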