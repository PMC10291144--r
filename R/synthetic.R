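#' Position-weight-matrix motif model for a synthetic HLA allele
#'
#' A motif model holds a 20 x 9 position-probability matrix plus anchor
#' constraints (position -> allowed residue set). Anchors zero out all
#' disallowed residues at that position. The default emulates HLA-A*01:01
#' binding preferences: acidic residues at position 3 and tyrosine at the
#' C-terminal anchor, so synthetic screens structurally resemble the
#' MAGEA3 scenario.
#'
#' @param anchors named list, names = positions ("3", "9"), values =
#'   character vectors of allowed residues.
#' @param allele allele label attached to generated peptides.
#' @param pwm optional 20 x 9 probability matrix (rows = [AA_ALPHABET] in
#'   order); default uniform before anchor masking.
#' @return An object of class `motif_model`.
#' @export
motif_model <- function(anchors = list(), allele = "HLA-A*01:01",
                        pwm = NULL) {
  if (is.null(pwm)) {
    pwm <- matrix(1 / 20, nrow = 20, ncol = 9,
                  dimnames = list(AA_ALPHABET, paste0("P", 1:9)))
  }
  stopifnot(is.matrix(pwm), nrow(pwm) == 20, ncol(pwm) == 9)
  rownames(pwm) <- rownames(pwm) %||% AA_ALPHABET
  pwm <- pwm[AA_ALPHABET, , drop = FALSE]
  for (p in names(anchors)) {
    allowed <- anchors[[p]]
    if (length(allowed) == 0 || !all(allowed %in% AA_ALPHABET)) {
      stop("anchor at position ", p,
           " must be a non-empty set of canonical residues", call. = FALSE)
    }
    pos <- as.integer(p)
    mask <- rownames(pwm) %in% allowed
    pwm[!mask, pos] <- 0
  }
  bad <- colSums(pwm) == 0
  if (any(bad)) {
    stop("motif has zero total probability at position(s) ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  pwm <- sweep(pwm, 2, colSums(pwm), "/")
  structure(list(pwm = pwm, anchors = anchors,
                 allele = normalize_hla(allele)),
            class = "motif_model")
}

#' @rdname motif_model
#' @export
hla_a01_motif <- function() {
  motif_model(anchors = list("3" = c("D", "E"), "9" = "Y"),
              allele = "HLA-A*01:01")
}

# anchor presets loosely modeled on well-known class I binding motifs;
# used to emulate a multi-allele pooled database
motif_presets <- function() {
  list(
    motif_model(list("3" = c("D", "E"), "9" = "Y"), "HLA-A*01:01"),
    motif_model(list("2" = c("L", "M"), "9" = c("V", "L")), "HLA-A*02:01"),
    motif_model(list("2" = "P", "9" = c("L", "F")), "HLA-B*07:02"),
    motif_model(list("2" = c("S", "T", "A"), "9" = c("W", "F")),
                "HLA-B*57:01"),
    motif_model(list("2" = c("Y", "R"), "9" = c("Y", "F", "L")),
                "HLA-C*07:01")
  )
}

#' Synthetic amino-acid property table
#'
#' Reproducible random scales over the 20 amino acids; a configurable
#' fraction of scales receives one missing value so the completeness
#' filter is exercised.
#'
#' @param n_scales number of scales (>= 2).
#' @param seed integer seed.
#' @param missing_fraction probability that a scale contains one missing
#'   value (default 0).
#' @return A [property_table()].
#' @export
synth_property_table <- function(n_scales, seed = 1, missing_fraction = 0) {
  if (!is.numeric(n_scales) || n_scales < 2) {
    stop("need n_scales >= 2", call. = FALSE)
  }
  n_scales <- as.integer(n_scales)
  local_seed(seed, {
    vals <- matrix(rnorm(20 * n_scales), nrow = 20,
                   dimnames = list(AA_ALPHABET,
                                   sprintf("SYN%04d", seq_len(n_scales))))
    if (missing_fraction > 0) {
      incomplete <- stats::runif(n_scales) < missing_fraction
      for (j in which(incomplete)) {
        vals[sample.int(20, 1), j] <- NA
      }
    }
    property_table(vals)
  })
}

#' Synthetic motif-constrained immunopeptidome
#'
#' Samples `n` unique 9-mers from a motif model (anchors enforced by
#' construction) and returns them as a single-allele database.
#'
#' @param motif a [motif_model()] (default [hla_a01_motif()]).
#' @param n number of unique peptides.
#' @param seed integer seed.
#' @return A `peptide_db` with `n` entries for the motif's allele.
#' @export
synth_peptidome <- function(motif = hla_a01_motif(), n = 1000, seed = 1) {
  stopifnot(inherits(motif, "motif_model"), n >= 1)
  n <- as.integer(n)
  capacity <- prod(colSums(motif$pwm > 0))
  if (capacity < n) {
    stop("motif too constrained: only ", capacity,
         " distinct peptides possible, ", n, " requested", call. = FALSE)
  }
  local_seed(seed, {
    peptides <- character(0)
    tries <- 0L
    while (length(peptides) < n && tries < 1000L) {
      batch <- max(2L * (n - length(peptides)), 64L)
      mat <- vapply(seq_len(9L), function(p) {
        sample(AA_ALPHABET, batch, replace = TRUE, prob = motif$pwm[, p])
      }, character(batch))
      peptides <- unique(c(peptides,
                           apply(mat, 1, paste, collapse = "")))
      tries <- tries + 1L
    }
    if (length(peptides) < n) {
      stop("motif saturated before reaching ", n, " unique peptides",
           call. = FALSE)
    }
    as_peptide_db(tibble(
      peptide = peptides[seq_len(n)], allele = motif$allele,
      source = "synthetic",
      gene = sprintf("SYNG%05d", seq_len(n))
    ))
  })
}

#' Pooled multi-allele synthetic database
#'
#' Concatenates motif-constrained peptidomes over several allele presets,
#' emulating an allele-diverse pooled immunopeptidome for allele-agnostic
#' Monte-Carlo null simulation.
#'
#' @param n_per_allele peptides per allele.
#' @param seed integer seed.
#' @return A `peptide_db` spanning five synthetic alleles.
#' @export
synth_multi_allele_db <- function(n_per_allele = 1000, seed = 1) {
  presets <- motif_presets()
  dbs <- Map(function(m, i) synth_peptidome(m, n_per_allele, seed + i),
             presets, seq_along(presets))
  as_peptide_db(bind_rows(lapply(dbs, as_tibble)))
}

#' Spiked off-target variants at an exact Hamming distance
#'
#' Generates peptides at exact Hamming distance `m_subs` from the query,
#' with substituted positions and replacement residues drawn uniformly.
#' When `count` equals the number of distinct variants they are enumerated
#' exactly once each (e.g. all 9 x 19 = 171 single-substitution variants).
#'
#' @param query a 9-mer sequence.
#' @param m_subs number of substituted positions (0..9).
#' @param count number of variants requested.
#' @param seed integer seed.
#' @return Character vector of `count` peptides, all at Hamming distance
#'   `m_subs` from `query`.
#' @export
spike_offtargets <- function(query, m_subs, count, seed = 1) {
  query <- validate_peptides(query)
  if (m_subs < 0 || m_subs > 9) {
    stop("m_subs must be in 0..9", call. = FALSE)
  }
  qres <- strsplit(query, "")[[1]]
  if (m_subs == 0) return(rep(query, count))
  total <- choose(9, m_subs) * 19^m_subs
  if (count > total) {
    stop("only ", total, " distinct variants exist at Hamming distance ",
         m_subs, "; ", count, " requested", call. = FALSE)
  }
  if (count == total && m_subs == 1L) {
    out <- unlist(lapply(1:9, function(p) {
      vapply(setdiff(AA_ALPHABET, qres[p]), function(r) {
        v <- qres; v[p] <- r; paste(v, collapse = "")
      }, character(1))
    }))
    return(unname(out))
  }
  local_seed(seed, {
    variants <- character(0)
    tries <- 0L
    while (length(variants) < count && tries < 10000L) {
      batch <- max(2L * (count - length(variants)), 32L)
      new <- vapply(seq_len(batch), function(...) {
        pos <- sample.int(9L, m_subs)
        v <- qres
        for (p in pos) v[p] <- sample(setdiff(AA_ALPHABET, qres[p]), 1)
        paste(v, collapse = "")
      }, character(1))
      variants <- unique(c(variants, new))
      tries <- tries + 1L
    }
    if (length(variants) < count) {
      stop("could not generate ", count, " distinct variants",
           call. = FALSE)
    }
    variants[seq_len(count)]
  })
}

#' Synthetic annotation tables
#'
#' `synth_expression_table()` draws per-gene pTPM profiles over `n_tissues`
#' tissues from a mixture of the five specificity archetypes
#' (tissue-enriched, group-enriched, tissue-enhanced, low-specificity,
#' not-expressed). `synth_binding_table()` draws log-normal IC50 values and
#' uniform immunogenicity scores per peptide.
#'
#' @param genes character vector of gene symbols.
#' @param n_tissues number of tissues (default 37).
#' @param seed integer seed.
#' @return A tibble in the annotation input conventions of
#'   [annotate_screen()].
#' @export
synth_expression_table <- function(genes, n_tissues = 37, seed = 1) {
  local_seed(seed, {
    tissues <- sprintf("tissue%02d", seq_len(n_tissues))
    rows <- lapply(genes, function(g) {
      arch <- sample(c("enriched", "group", "enhanced", "low", "off"), 1)
      base <- stats::rexp(n_tissues, rate = 1 / 5)
      v <- switch(arch,
        enriched = { base[1] <- max(base) * 8 + 10; base },
        group = { base[1:3] <- max(base) * 8 + 10; base },
        enhanced = { base <- base + 2; base[1] <- mean(base) * 7; base },
        low = base + 2,
        off = stats::runif(n_tissues, 0, 0.5)
      )
      setNames(as.list(round(v[sample.int(n_tissues)], 2)), tissues)
    })
    out <- bind_rows(rows)
    out$gene <- genes
    out[, c("gene", tissues)]
  })
}

#' @rdname synth_expression_table
#' @param peptides character vector of 9-mers.
#' @param allele allele label.
#' @export
synth_binding_table <- function(peptides, allele = "HLA-A*01:01",
                                seed = 1) {
  local_seed(seed, {
    tibble(
      peptide = peptides,
      allele = normalize_hla(allele),
      ic50_nM = round(stats::rlnorm(length(peptides),
                                    meanlog = log(200), sdlog = 1.5), 2),
      immunogenicity = round(stats::runif(length(peptides)), 3)
    )
  })
}
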