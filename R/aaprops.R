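#' Amino-acid property tables
#'
#' A property table holds one column per biochemical scale (an AAIndex entry
#' or any user-supplied scale) and one row per canonical amino acid. Missing
#' values are preserved; scales containing any missing value are excluded
#' later by the completeness filter in [build_property_matrix()].
#'
#' @param values numeric matrix with the 20 canonical amino acids as rows
#'   (one-letter code) and scales as columns.
#' @param provenance optional character vector (one per scale) recording the
#'   source of each scale, e.g. an AAIndex accession and title.
#'
#' @return An object of class `property_table`.
#' @export
property_table <- function(values, provenance = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || !setequal(rownames(values), AA_ALPHABET) ||
      anyDuplicated(rownames(values))) {
    stop("rows must be the 20 canonical amino acids, each exactly once",
         call. = FALSE)
  }
  values <- values[AA_ALPHABET, , drop = FALSE]
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("scale%03d", seq_len(ncol(values)))
  }
  if (is.null(provenance)) provenance <- colnames(values)
  stopifnot(length(provenance) == ncol(values))
  structure(
    list(values = values, provenance = as.character(provenance)),
    class = "property_table"
  )
}

#' @export
print.property_table <- function(x, ...) {
  nc <- ncol(x$values)
  cat("<property_table> ", nc, " scales x 20 amino acids (",
      sum(n_complete_scales(x)), " complete)\n", sep = "")
  invisible(x)
}

n_complete_scales <- function(table) {
  colSums(!is.finite(table$values)) == 0
}

#' Parse an AAIndex1 flat file
#'
#' Reads the AAIndex1 record format: each entry starts with an `H` accession
#' line and carries its 20 per-residue values on the two lines following the
#' `I` header, in the fixed residue order
#' `A R N D C Q E G H I` / `L K M F P S T W Y V`. `NA` values are preserved
#' as missing so the completeness filter can drop those scales later.
#'
#' @param path path to an AAIndex1-format file.
#' @return A [property_table()] with one column per AAIndex entry, named by
#'   accession.
#' @export
parse_aaindex1 <- function(path) {
  lines <- readLines(path)
  rec_end <- grepl("^//", lines)
  rec_id <- cumsum(c(TRUE, utils::head(rec_end, -1)))
  records <- split(lines, rec_id)
  records <- Filter(function(r) any(grepl("^H ", r)), records)
  if (length(records) == 0L) {
    stop("no AAIndex records found in ", path, call. = FALSE)
  }
  cols <- lapply(records, function(rec) {
    acc <- sub("^H\\s+", "", rec[grepl("^H ", rec)][1])
    desc <- if (any(grepl("^D ", rec))) {
      sub("^D\\s+", "", rec[grepl("^D ", rec)][1])
    } else ""
    i_at <- which(grepl("^I ", rec))
    if (length(i_at) != 1L || i_at + 2L > length(rec)) {
      stop("malformed AAIndex record ", acc, ": missing I line", call. = FALSE)
    }
    tokens <- unlist(strsplit(trimws(rec[c(i_at + 1L, i_at + 2L)]), "\\s+"))
    if (length(tokens) != 20L) {
      stop("malformed AAIndex record ", acc, ": expected 20 values, got ",
           length(tokens), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(ifelse(tokens == "NA", NA, tokens)))
    bad <- tokens != "NA" & is.na(vals)
    if (any(bad)) {
      stop("malformed AAIndex record ", acc, ": non-numeric value '",
           tokens[bad][1], "'", call. = FALSE)
    }
    list(acc = acc, desc = desc, vals = vals)
  })
  values <- vapply(cols, `[[`, numeric(20), "vals")
  rownames(values) <- AA_ALPHABET
  colnames(values) <- vapply(cols, `[[`, character(1), "acc")
  property_table(values,
                 provenance = paste0(colnames(values), ": ",
                                     vapply(cols, `[[`, character(1), "desc")))
}

#' Build a property table from the packaged AAIndex collection
#'
#' Uses the AAIndex release 9.1 data shipped with the seqinr package
#' (544 scales), so the descriptor space can be built with no downloads.
#'
#' @return A [property_table()] with 544 scales.
#' @export
aaindex_property_table <- function() {
  env <- new.env(parent = emptyenv())
  utils::data("aaindex", package = "seqinr", envir = env)
  aaindex <- env$aaindex
  values <- vapply(aaindex, function(e) unname(e$I[AA_THREE]), numeric(20))
  rownames(values) <- AA_ALPHABET
  colnames(values) <- vapply(aaindex, `[[`, character(1), "H")
  property_table(values,
                 provenance = paste0(colnames(values), ": ",
                                     vapply(aaindex, `[[`, character(1), "D")))
}

#' Build the PCA-reduced biochemical descriptor matrix
#'
#' Scales with missing values are dropped, each remaining scale is
#' standardized to zero mean and unit variance across the 20 amino acids,
#' and the amino acids (as observations) are projected onto principal
#' components of that standardized space. The smallest number of components
#' whose cumulative explained variance reaches `variance_target` is
#' retained; the 20 x K component scores become the coordinate system in
#' which peptides are encoded and compared.
#'
#' @param table a [property_table()].
#' @param variance_target fraction of variance the retained components must
#'   explain jointly, in (0, 1].
#' @return An object of class `property_matrix` with fields `coords`
#'   (20 x K), `explained_variance` (K fractions), `variance_target`,
#'   `n_source_scales`, `n_dropped`, `rds_scale` and `matrix_id`.
#' @export
build_property_matrix <- function(table, variance_target = 0.95) {
  stopifnot(inherits(table, "property_table"))
  if (!is.numeric(variance_target) || length(variance_target) != 1 ||
      variance_target <= 0 || variance_target > 1) {
    stop("`variance_target` must be in (0, 1]", call. = FALSE)
  }
  complete <- n_complete_scales(table)
  vals <- table$values[, complete, drop = FALSE]
  n_dropped <- sum(!complete)
  constant <- apply(vals, 2, function(v) sd(v) == 0)
  n_constant <- sum(constant)
  vals <- vals[, !constant, drop = FALSE]
  if (ncol(vals) < 2L) {
    stop("need at least 2 complete scales to build a matrix (have ",
         ncol(vals), ")", call. = FALSE)
  }
  z <- scale(vals)                       # 20 AA x S, each scale z-scored
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  frac <- ev / sum(ev)
  k <- which(cumsum(frac) >= variance_target - 1e-12)[1]
  coords <- pc$x[, seq_len(k), drop = FALSE]
  rownames(coords) <- AA_ALPHABET
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(
    list(
      coords = coords,
      explained_variance = frac[seq_len(k)],
      explained_variance_all = frac,
      variance_target = variance_target,
      n_source_scales = ncol(table$values),
      n_dropped = n_dropped,
      n_constant = n_constant,
      rds_scale = 1,
      matrix_id = sprintf("aapca_s%d_k%d_v%g", ncol(vals), k, variance_target)
    ),
    class = "property_matrix"
  )
}

#' @export
print.property_matrix <- function(x, ...) {
  cat("<property_matrix> ", x$matrix_id, "\n",
      "  20 amino acids x ", ncol(x$coords), " components (",
      round(100 * sum(x$explained_variance), 2), "% variance, target ",
      100 * x$variance_target, "%)\n",
      "  built from ", x$n_source_scales, " scales (", x$n_dropped,
      " dropped for missing values); rds_scale = ",
      signif(x$rds_scale, 6), "\n", sep = "")
  invisible(x)
}

#' Published worked relatedness values used for scale anchoring
#'
#' The two cross-reactive peptide pairs with published relatedness scores
#' whose sequences are available in full: the MAGEA3/MAGEA6 pair (single
#' conservative L→V substitution at position 8, RdS 1.35) and the
#' MAGEA3/NOP53 pair (RdS 12.95). Used by [calibrate_rds_scale()] to anchor
#' the absolute scale of the descriptor space.
#'
#' @return A data frame with columns `a`, `b`, `value`.
#' @export
reference_rds_pairs <- function() {
  data.frame(
    a = c("EVDPIGHLY", "EVDPIGHLY"),
    b = c("EVDPIGHVY", "EVAPAGASY"),
    value = c(1.35, 12.95),
    stringsAsFactors = FALSE
  )
}

#' Calibrate the relatedness scale of a descriptor matrix
#'
#' PCA fixes the geometry of the descriptor space but not its absolute
#' scale, which depends on unknowable preprocessing conventions of the
#' reference implementation. A single multiplicative constant is fitted by
#' least squares so that uniform-weight relatedness scores of the reference
#' pairs match their published values; the matrix coordinates are rescaled
#' by its square root and the constant is recorded in `rds_scale`.
#'
#' @param matrix a `property_matrix`.
#' @param reference data frame with columns `a`, `b` (9-mer sequences) and
#'   `value` (target RdS); defaults to [reference_rds_pairs()].
#' @return The calibrated `property_matrix`.
#' @export
calibrate_rds_scale <- function(matrix, reference = reference_rds_pairs()) {
  stopifnot(inherits(matrix, "property_matrix"))
  stopifnot(all(c("a", "b", "value") %in% names(reference)),
            nrow(reference) >= 1)
  raw <- mapply(function(a, b) {
    relatedness(encode_peptide(a, matrix), encode_peptide(b, matrix))
  }, reference$a, reference$b)
  scale_c <- sum(raw * reference$value) / sum(raw^2)
  matrix$coords <- matrix$coords * sqrt(scale_c)
  matrix$rds_scale <- matrix$rds_scale * scale_c
  matrix$matrix_id <- paste0(matrix$matrix_id, "_cal")
  matrix
}

#' Default calibrated descriptor matrix
#'
#' Builds (and caches for the session) the descriptor matrix from the
#' packaged AAIndex collection at the default 95% variance target, scale
#' calibrated against [reference_rds_pairs()].
#'
#' @param variance_target fraction of variance to retain (default 0.95).
#' @param calibrate apply [calibrate_rds_scale()] (default TRUE).
#' @return A `property_matrix`.
#' @export
default_property_matrix <- function(variance_target = 0.95, calibrate = TRUE) {
  key <- sprintf("pm_%g_%d", variance_target, calibrate)
  if (!is.null(.xreact_cache[[key]])) return(.xreact_cache[[key]])
  pm <- build_property_matrix(aaindex_property_table(), variance_target)
  if (calibrate) pm <- calibrate_rds_scale(pm)
  .xreact_cache[[key]] <- pm
  pm
}

#' Residue-residue biochemical correlation
#'
#' Pearson correlations between the per-residue descriptor vectors, either
#' component scores of a `property_matrix` or raw (complete) scales of a
#' `property_table`. High values recover expected biochemical kinship,
#' e.g. glutamic vs aspartic acid.
#'
#' @param x a `property_matrix` or `property_table`.
#' @return A symmetric 20 x 20 correlation matrix with unit diagonal.
#' @export
residue_correlation <- function(x) {
  if (inherits(x, "property_matrix")) {
    m <- x$coords
  } else if (inherits(x, "property_table")) {
    m <- x$values[, n_complete_scales(x), drop = FALSE]
  } else if (is.matrix(x) && is.numeric(x)) {
    m <- x
  } else {
    stop("`x` must be a property_matrix, property_table, or numeric matrix",
         call. = FALSE)
  }
  sds <- apply(m, 1, sd)
  if (any(sds == 0)) {
    stop("correlation undefined for zero-variance residue vector(s): ",
         paste(rownames(m)[sds == 0], collapse = ", "), call. = FALSE)
  }
  cor(t(m))
}

#' Write / read a descriptor matrix as a TSV artifact
#'
#' The artifact is a plain TSV (one row per amino acid, one column per
#' component) preceded by `#`-prefixed metadata lines, so downstream
#' screening can run without AAIndex present.
#'
#' @param matrix a `property_matrix`.
#' @param path output (input) file path.
#' @return `write_property_matrix` returns `path` invisibly;
#'   `read_property_matrix` returns a `property_matrix`.
#' @export
write_property_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "property_matrix"))
  meta <- c(
    paste0("# matrix_id=", matrix$matrix_id),
    paste0("# n_source_scales=", matrix$n_source_scales),
    paste0("# n_dropped=", matrix$n_dropped),
    paste0("# variance_target=", format(matrix$variance_target, digits = 17)),
    paste0("# k=", ncol(matrix$coords)),
    paste0("# rds_scale=", format(matrix$rds_scale, digits = 17)),
    paste0("# explained_variance=",
           paste(format(matrix$explained_variance, digits = 17),
                 collapse = ","))
  )
  body <- apply(cbind(residue = rownames(matrix$coords),
                      format(matrix$coords, digits = 17)), 1,
                paste, collapse = "\t")
  header <- paste(c("residue", colnames(matrix$coords)), collapse = "\t")
  writeLines(c(meta, header, body), path)
  invisible(path)
}

#' @rdname write_property_matrix
#' @export
read_property_matrix <- function(path) {
  lines <- readLines(path)
  meta_lines <- lines[startsWith(lines, "#")]
  meta <- strsplit(sub("^#\\s*", "", meta_lines), "=", fixed = TRUE)
  meta <- setNames(vapply(meta, `[[`, character(1), 2),
                   vapply(meta, `[[`, character(1), 1))
  tab <- utils::read.table(text = lines[!startsWith(lines, "#")],
                           header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  coords <- as.matrix(tab[, -1, drop = FALSE])
  rownames(coords) <- tab$residue
  coords <- coords[AA_ALPHABET, , drop = FALSE]
  ev <- as.numeric(strsplit(meta[["explained_variance"]], ",")[[1]])
  structure(
    list(
      coords = coords,
      explained_variance = ev,
      explained_variance_all = ev,
      variance_target = as.numeric(meta[["variance_target"]]),
      n_source_scales = as.integer(meta[["n_source_scales"]]),
      n_dropped = as.integer(meta[["n_dropped"]]),
      n_constant = NA_integer_,
      rds_scale = as.numeric(meta[["rds_scale"]]),
      matrix_id = meta[["matrix_id"]]
    ),
    class = "property_matrix"
  )
}
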