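# fixture builders shared across the suite; everything is generated in code

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# write an AAIndex1-format flat file from a named list of length-20 numeric
# vectors (NA allowed), values in the canonical residue order
write_aaindex_fixture <- function(scales, path = tempfile(fileext = ".txt")) {
  fmt <- function(v) {
    vapply(v, function(x) if (is.na(x)) "NA" else sprintf("%.3f", x),
           character(1))
  }
  lines <- unlist(lapply(names(scales), function(acc) {
    v <- fmt(scales[[acc]])
    c(paste0("H ", acc),
      paste0("D synthetic fixture scale ", acc),
      "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
      paste0("  ", paste(v[1:10], collapse = "  ")),
      paste0("  ", paste(v[11:20], collapse = "  ")),
      "//")
  }))
  writeLines(lines, path)
  path
}

random_scales <- function(n, seed) {
  set.seed(seed)
  stats::setNames(
    lapply(seq_len(n), function(i) round(stats::rnorm(20), 3)),
    sprintf("FIX%04d", seq_len(n))
  )
}

# peptides at all single-residue substitutions of `q` at one position
subs_at <- function(q, pos) {
  res <- strsplit(q, "")[[1]]
  vapply(setdiff(AA20, res[pos]), function(r) {
    v <- res
    v[pos] <- r
    paste(v, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# brute-force screening oracle: re-encode, re-score pairwise, re-sort;
# deliberately avoids the vectorized lookup used by cross_screen()
brute_force_screen <- function(query, peptides, matrix, w = rep(1, 9)) {
  qp <- encode_peptide(query, matrix)
  rds <- vapply(peptides, function(p) {
    pp <- encode_peptide(p, matrix)
    total <- 0
    for (i in 1:9) {
      d2 <- 0
      for (k in seq_len(ncol(matrix$coords))) {
        d2 <- d2 + (qp[i, k] - pp[i, k])^2
      }
      total <- total + w[i] * d2
    }
    total / 9
  }, numeric(1), USE.NAMES = FALSE)
  ord <- order(rds, peptides)
  data.frame(peptide = peptides[ord], rds = rds[ord],
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

# small contact-record tibble for recount oracles
random_contact_records <- function(n, n_frames, seed) {
  set.seed(seed)
  tibble::tibble(
    frame = sample.int(n_frames, n, replace = TRUE) - 1L,
    interaction_type = sample(contact_interaction_types(), n,
                              replace = TRUE),
    partner_chain = sample(c("D", "E"), n, replace = TRUE),
    partner_resid = sample(20:60, n, replace = TRUE),
    peptide_position = sample.int(9L, n, replace = TRUE)
  )
}
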