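#' Interaction types recognized in contact tables
#'
#' The closed vocabulary of residue-residue interaction types emitted by
#' GetContacts-style analyses: hydrogen-bond related (`hbbb`, `hbsb`,
#' `hbss`), salt bridge (`sb`), pi-cation (`pc`), pi-stacking (`ps`),
#' t-stacking (`ts`), hydrophobic (`hp`), and van der Waals (`vdw`).
#'
#' @return Character vector of the nine interaction type codes.
#' @export
contact_interaction_types <- function() {
  c("hbbb", "hbsb", "hbss", "sb", "pc", "ps", "ts", "hp", "vdw")
}

parse_atom <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)
  tibble(
    chain = vapply(parts, `[`, character(1), 1),
    resname = vapply(parts, `[`, character(1), 2),
    resid = suppressWarnings(
      as.integer(vapply(parts, `[`, character(1), 3)))
  )
}

#' Parse a residue-contact table into TCR-peptide contact records
#'
#' Reads a GetContacts-style TSV (`frame`, `interaction_type`, `atom_1`,
#' `atom_2`, atoms encoded `chain:resname:resid[:atom]`; `#` comment lines
#' ignored), keeps only rows where exactly one side lies on the peptide
#' chain, and maps peptide residue numbers to positions 1..L. Contacts
#' outside 1..L are skipped with a warning; interaction types outside the
#' closed vocabulary are a parse error.
#'
#' @param path path to the contact table.
#' @param peptide_chain chain identifier of the peptide in the structure.
#' @param L peptide length (default 9).
#' @return A tibble of contact records: `frame`, `interaction_type`,
#'   `partner_chain`, `partner_resid`, `peptide_position`.
#' @export
parse_contacts <- function(path, peptide_chain, L = 9) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble(frame = integer(0), interaction_type = character(0),
                  partner_chain = character(0), partner_resid = integer(0),
                  peptide_position = integer(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, integer(1))
  if (any(nf < 4L)) {
    stop("malformed contact line (need >= 4 tab-separated fields): '",
         lines[nf < 4L][1], "'", call. = FALSE)
  }
  frame <- as.integer(vapply(fields, `[`, character(1), 1))
  itype <- vapply(fields, `[`, character(1), 2)
  bad_type <- !itype %in% contact_interaction_types()
  if (any(bad_type)) {
    stop("unknown interaction type '", itype[bad_type][1], "'",
         call. = FALSE)
  }
  a1 <- parse_atom(vapply(fields, `[`, character(1), 3))
  a2 <- parse_atom(vapply(fields, `[`, character(1), 4))
  on_pep1 <- a1$chain == peptide_chain
  on_pep2 <- a2$chain == peptide_chain
  keep <- xor(on_pep1, on_pep2)   # TCR<->peptide rows only
  pep <- ifelse(on_pep1, a1$resid, a2$resid)
  partner_chain <- ifelse(on_pep1, a2$chain, a1$chain)
  partner_resid <- ifelse(on_pep1, a2$resid, a1$resid)
  rec <- tibble(
    frame = frame, interaction_type = itype,
    partner_chain = partner_chain, partner_resid = partner_resid,
    peptide_position = pep
  )[keep, ]
  out_of_range <- rec$peptide_position < 1L | rec$peptide_position > L |
    is.na(rec$peptide_position)
  if (any(out_of_range)) {
    warning(sum(out_of_range), " contact(s) outside peptide positions 1..",
            L, " skipped", call. = FALSE)
    rec <- rec[!out_of_range, ]
  }
  rec
}

#' Build a per-position weight vector from contact records
#'
#' Counts contacts per peptide position (cumulative over interaction types
#' and frames) and substitutes a pseudo-count at positions with no TCR
#' interaction, yielding the contact-map penalty vector used for
#' TCR-centered screening. With the static A3A/MAGEA3 crystal contacts
#' (counts 3, 4, 2, 1, 1 at positions 1, 4, 5, 7, 8) this reproduces the
#' CM-crystal vector (3.0, 0.5, 0.5, 4.0, 2.0, 0.5, 1.0, 1.0, 0.5).
#'
#' @param records contact records from [parse_contacts()], or a named/
#'   position-indexed numeric vector of per-position counts.
#' @param L peptide length (default 9).
#' @param pseudo positive pseudo-count for positions without contacts
#'   (default 0.5).
#' @param per_frame_dedup if TRUE (default), a (position, type, partner
#'   residue) contact is counted once per frame; if FALSE every record row
#'   counts.
#' @param provenance "crystal", "dynamic", or "custom"; inferred from the
#'   frame column when records are given.
#' @return An object of class `contact_map` with fields `counts`, `weights`
#'   (a [weight_vector()]), `pseudo_count`, `provenance`.
#' @export
build_contact_weights <- function(records, L = 9, pseudo = 0.5,
                                  per_frame_dedup = TRUE,
                                  provenance = NULL) {
  if (!is.numeric(pseudo) || pseudo <= 0) {
    stop("pseudo-count must be > 0", call. = FALSE)
  }
  if (is.numeric(records)) {
    counts <- numeric(L)
    pos <- as.integer(names(records) %||% seq_along(records))
    if (any(pos < 1L | pos > L)) {
      stop("counts reference positions outside 1..", L, call. = FALSE)
    }
    counts[pos] <- counts[pos] + as.numeric(records)
    provenance <- provenance %||% "custom"
  } else {
    stopifnot(is.data.frame(records))
    if (nrow(records) > 0 &&
        any(records$peptide_position < 1L | records$peptide_position > L)) {
      stop("records reference positions outside 1..", L, call. = FALSE)
    }
    rec <- records
    if (per_frame_dedup && nrow(rec) > 0) {
      rec <- distinct(rec, .data$frame, .data$interaction_type,
                      .data$partner_chain, .data$partner_resid,
                      .data$peptide_position)
    }
    counts <- tabulate(rec$peptide_position, nbins = L)
    provenance <- provenance %||%
      if (nrow(rec) > 0 && any(rec$frame > 0)) "dynamic" else "crystal"
  }
  w <- ifelse(counts > 0, counts, pseudo)
  structure(
    list(counts = counts,
         weights = weight_vector(w, paste0("CM-", provenance)),
         pseudo_count = pseudo, provenance = provenance),
    class = "contact_map"
  )
}

#' @export
print.contact_map <- function(x, ...) {
  cat("<contact_map> provenance: ", x$provenance, ", pseudo-count ",
      x$pseudo_count, "\n  counts:  ",
      paste(format(x$counts), collapse = " "), "\n  weights: ",
      paste(format(as.numeric(x$weights)), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Apply knowledge-based weight overrides to a contact map
#'
#' Replaces weights at selected positions (e.g. to encode HLA anchor
#' positions that structural contacts alone under-weight); non-overridden
#' positions are untouched and provenance becomes "custom".
#'
#' @param map a `contact_map`.
#' @param overrides named numeric vector, names = positions, values =
#'   positive weights, e.g. `c("3" = 2, "9" = 2)`.
#' @return A new `contact_map`.
#' @export
apply_weight_overrides <- function(map, overrides) {
  stopifnot(inherits(map, "contact_map"))
  w <- as.numeric(map$weights)
  if (length(overrides) > 0) {
    pos <- as.integer(names(overrides))
    if (any(is.na(pos)) || any(pos < 1L | pos > length(w))) {
      stop("override positions must be within 1..", length(w),
           call. = FALSE)
    }
    if (any(!is.finite(overrides) | overrides <= 0)) {
      stop("override weights must be > 0", call. = FALSE)
    }
    w[pos] <- as.numeric(overrides)
  }
  structure(
    list(counts = map$counts,
         weights = weight_vector(w, "CM-custom"),
         pseudo_count = map$pseudo_count, provenance = "custom"),
    class = "contact_map"
  )
}

#' Reference A3A TCR contact maps for the MAGEA3 scenario
#'
#' `cm_crystal()` is the penalty vector derived from the static
#' A3A/MAGEA3/HLA-A*01:01 crystal contacts (per-position counts with
#' pseudo-count 0.5); `cm_custom()` additionally raises the HLA-A*01 anchor
#' positions 3 and 9 to 2.0 based on binding-motif knowledge.
#'
#' @return A `contact_map`.
#' @export
cm_crystal <- function() {
  build_contact_weights(c("1" = 3, "4" = 4, "5" = 2, "7" = 1, "8" = 1),
                        provenance = "crystal")
}

#' @rdname cm_crystal
#' @export
cm_custom <- function() {
  apply_weight_overrides(cm_crystal(), c("3" = 2.0, "9" = 2.0))
}
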