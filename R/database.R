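#' Normalize HLA class I allele names
#'
#' Accepts common encodings ("A0101", "HLA-A*01:01:01", "A*01:01") and
#' returns the two-field form "HLA-A*01:01"; extra typing fields are
#' truncated because screening is per two-field allele.
#'
#' @param x character vector of allele names.
#' @return Normalized character vector.
#' @export
normalize_hla <- function(x) {
  x <- toupper(trimws(x))
  x <- sub("^HLA-", "", x)
  # compact form like A0101 / B5701
  compact <- grepl("^[ABC][0-9]{4,}$", x)
  x[compact] <- sub("^([ABC])([0-9]{2})([0-9]{2}).*$", "\\1*\\2:\\3",
                    x[compact])
  m <- regmatches(x, regexec("^([ABC])\\*?([0-9]+):?([0-9]+)", x))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) {
    stop("unrecognized HLA allele format: '", x[bad][1], "'", call. = FALSE)
  }
  vapply(m, function(g) {
    sprintf("HLA-%s*%02d:%02d", g[2], as.integer(g[3]), as.integer(g[4]))
  }, character(1))
}

db_columns <- c("peptide", "allele", "source", "gene", "ic50_nM",
                "immunogenicity")

read_peptide_source <- function(path, source = NULL) {
  base <- sub("\\.gz$", "", basename(path))
  if (grepl("\\.(fa|fasta)$", base, ignore.case = TRUE)) {
    seqs <- Biostrings::readAAStringSet(path)
    headers <- names(seqs)
    allele <- regmatches(headers, regexpr("allele=[^ ]+", headers))
    allele <- sub("^allele=", "", allele)
    if (length(allele) != length(seqs)) {
      stop("FASTA source ", basename(path),
           ": every header needs an 'allele=' tag", call. = FALSE)
    }
    gene <- rep(NA_character_, length(seqs))
    gm <- regexpr("gene=[^ ]+", headers)
    gene[gm > 0] <- sub("^gene=", "", regmatches(headers, gm))
    tibble(peptide = unname(as.character(seqs)), allele = allele,
           source = source %||% basename(path), gene = gene,
           ic50_nM = NA_real_, immunogenicity = NA_real_)
  } else {
    delim <- if (grepl("\\.csv$", base, ignore.case = TRUE)) "," else "\t"
    raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                             progress = FALSE)
    if (!all(c("peptide", "allele") %in% names(raw))) {
      stop("tabular source ", basename(path),
           " must have 'peptide' and 'allele' columns", call. = FALSE)
    }
    tibble(
      peptide = as.character(raw$peptide),
      allele = as.character(raw$allele),
      source = if ("source" %in% names(raw)) as.character(raw$source)
               else source %||% basename(path),
      gene = if ("gene" %in% names(raw)) as.character(raw$gene)
             else NA_character_,
      ic50_nM = if ("ic50_nM" %in% names(raw)) as.numeric(raw$ic50_nM)
                else NA_real_,
      immunogenicity = if ("immunogenicity" %in% names(raw))
        as.numeric(raw$immunogenicity) else NA_real_
    )
  }
}

#' Assemble a non-redundant immunopeptidome database
#'
#' Reads one or more peptide sources (TSV/CSV with `peptide, allele,
#' source[, gene, ic50_nM, immunogenicity]` columns, or FASTA with
#' `allele=` header tags; gzip transparent), drops non-9-mers and
#' non-canonical sequences, normalizes allele names, and merges duplicate
#' (peptide, allele) pairs with source labels concatenated. The filter log
#' (attribute `filter_log`) accounts for every input row exactly:
#' input = kept + length_filtered + alphabet_filtered + merged.
#'
#' @param sources character vector of file paths, or a data frame already in
#'   column convention.
#' @param source optional source label for files lacking a source column.
#' @return A `peptide_db` tibble.
#' @export
load_peptides <- function(sources, source = NULL) {
  raw <- if (is.data.frame(sources)) {
    df <- as_tibble(sources)
    for (col in db_columns) {
      if (!col %in% names(df)) {
        df[[col]] <- if (col %in% c("ic50_nM", "immunogenicity"))
          NA_real_ else if (col == "source") source %||% "user" else
            NA_character_
      }
    }
    df[db_columns]
  } else {
    bind_rows(lapply(sources, read_peptide_source, source = source))
  }
  as_peptide_db(raw)
}

#' @rdname load_peptides
#' @param entries data frame with at least `peptide` and `allele` columns.
#' @export
as_peptide_db <- function(entries) {
  entries <- as_tibble(entries)
  stopifnot(all(c("peptide", "allele") %in% names(entries)))
  for (col in db_columns) {
    if (!col %in% names(entries)) {
      entries[[col]] <- if (col %in% c("ic50_nM", "immunogenicity"))
        NA_real_ else NA_character_
    }
  }
  entries <- entries[db_columns]
  n_input <- nrow(entries)
  entries$peptide <- toupper(entries$peptide)
  len_ok <- nchar(entries$peptide) == 9L
  n_length <- sum(!len_ok)
  entries <- entries[len_ok, ]
  alpha_ok <- grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"),
                    entries$peptide)
  n_alpha <- sum(!alpha_ok)
  entries <- entries[alpha_ok, ]
  if (nrow(entries) == 0L) {
    stop("no valid 9-mer entries remain after filtering", call. = FALSE)
  }
  entries$allele <- normalize_hla(entries$allele)
  merged <- entries %>%
    group_by(.data$peptide, .data$allele) %>%
    summarise(
      source = paste(sort(unique(stats::na.omit(.data$source))),
                     collapse = "|"),
      gene = if (all(is.na(.data$gene))) NA_character_ else
        paste(sort(unique(stats::na.omit(.data$gene))), collapse = "|"),
      ic50_nM = if (all(is.na(.data$ic50_nM))) NA_real_ else
        min(.data$ic50_nM, na.rm = TRUE),
      immunogenicity = if (all(is.na(.data$immunogenicity))) NA_real_ else
        max(.data$immunogenicity, na.rm = TRUE),
      .groups = "drop"
    ) %>%
    arrange(.data$allele, .data$peptide)
  merged$source[merged$source == ""] <- "unknown"
  n_merged <- n_input - n_length - n_alpha - nrow(merged)
  structure(
    merged,
    filter_log = c(input = n_input, kept = nrow(merged),
                   length_filtered = n_length, alphabet_filtered = n_alpha,
                   merged_duplicates = n_merged),
    class = c("peptide_db", class(merged))
  )
}

#' @export
print.peptide_db <- function(x, ...) {
  log <- attr(x, "filter_log")
  cat("<peptide_db> ", nrow(x), " unique (peptide, allele) entries, ",
      length(unique(x$allele)), " alleles\n", sep = "")
  if (!is.null(log)) {
    cat("  filter log: ", paste(names(log), log, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  NextMethod()
}

#' Subset a database to one HLA allele
#'
#' @param db a `peptide_db`.
#' @param allele allele name in any accepted encoding.
#' @return A `peptide_db` restricted to that allele.
#' @export
subset_allele <- function(db, allele) {
  allele <- normalize_hla(allele)
  avail <- unique(db$allele)
  if (!allele %in% avail) {
    stop("allele ", allele, " not in database; available: ",
         paste(sort(avail), collapse = ", "), call. = FALSE)
  }
  out <- db[db$allele == allele, ]
  attr(out, "filter_log") <- NULL
  class(out) <- class(db)
  out
}

#' Summarize an immunopeptidome database
#'
#' Per-allele counts, per-locus entry proportions (HLA-A/B/C), and the
#' number of distinct sequences shared across loci.
#'
#' @param db a `peptide_db`.
#' @return A list with `per_allele` (tibble allele/n), `per_locus` (tibble
#'   locus/n/proportion, proportions summing to 1), and `cross_locus_shared`
#'   (integer count of sequences presented by more than one locus).
#' @export
db_summary <- function(db) {
  if (nrow(db) == 0L) stop("empty database", call. = FALSE)
  per_allele <- db %>% count(.data$allele, name = "n") %>%
    arrange(dplyr::desc(.data$n))
  locus <- sub("^HLA-([ABC]).*$", "\\1", db$allele)
  per_locus <- tibble(locus = locus) %>%
    count(.data$locus, name = "n") %>%
    mutate(proportion = .data$n / sum(.data$n))
  shared <- tibble(peptide = db$peptide, locus = locus) %>%
    distinct() %>%
    count(.data$peptide, name = "n_loci") %>%
    filter(.data$n_loci > 1L) %>%
    nrow()
  list(per_allele = per_allele, per_locus = per_locus,
       cross_locus_shared = shared)
}
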