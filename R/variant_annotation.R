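# Variant nomenclature and annotation input. Only the HGVS subset needed
# for ABCA4 cDNA/protein descriptions of the supported kinds is parsed;
# anything outside it raises rather than guessing, so that a misparsed
# name can never silently feed the rule engine.

AA3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
         "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
         "Tyr", "Val")

#' Parse a cDNA change (HGVS subset)
#'
#' Supported forms: exonic substitutions (`c.614G>T`), intron-offset
#' substitutions (`c.5461-10T>C`, `c.3607+771G>A`), deletions (`c.4734del`)
#' and duplications. An intron offset of 0 means the position is exonic.
#'
#' @param text A single string beginning with `"c."`.
#' @return A list of class `cdna_change` with `position`, `intron_offset`,
#'   `ref`, `alt`, `kind` (substitution, deletion, duplication).
#' @export
parse_cdna <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  bad <- function() {
    rlang::abort(paste0("cannot parse cDNA change: '", text, "'"),
                 class = "abca4_parse_error")
  }
  if (!startsWith(text, "c.")) bad()
  body <- sub("^c\\.", "", text)
  m <- regmatches(body,
                  regexec("^(\\d+)([+-]\\d+)?([ACGT]+)>([ACGT]+)$", body))[[1]]
  if (length(m) > 0) {
    return(structure(list(
      position = as.integer(m[2]),
      intron_offset = if (m[3] == "") 0L else as.integer(m[3]),
      ref = m[4], alt = m[5], kind = "substitution"
    ), class = "cdna_change"))
  }
  m <- regmatches(body,
                  regexec("^(\\d+)([+-]\\d+)?(?:_(\\d+)([+-]\\d+)?)?(del|dup)([ACGT]*)$",
                          body))[[1]]
  if (length(m) > 0) {
    return(structure(list(
      position = as.integer(m[2]),
      intron_offset = if (m[3] == "") 0L else as.integer(m[3]),
      ref = if (m[7] == "") NA_character_ else m[7],
      alt = NA_character_,
      kind = if (m[6] == "del") "deletion" else "duplication"
    ), class = "cdna_change"))
  }
  bad()
}

#' Serialise a parsed cDNA change back to its HGVS string
#'
#' @param x A `cdna_change` as returned by [parse_cdna()].
#' @return A single string; `format_cdna(parse_cdna(s))` round-trips every
#'   supported form.
#' @export
format_cdna <- function(x) {
  stopifnot(inherits(x, "cdna_change"))
  off <- if (x$intron_offset == 0L) "" else sprintf("%+d", x$intron_offset)
  if (x$kind == "substitution") {
    return(paste0("c.", x$position, off, x$ref, ">", x$alt))
  }
  suffix <- if (x$kind == "deletion") "del" else "dup"
  paste0("c.", x$position, off, suffix,
         if (is.na(x$ref)) "" else x$ref)
}

parse_protein_single <- function(token, original) {
  bad <- function() {
    rlang::abort(paste0("cannot parse protein change: '", original, "'"),
                 class = "abca4_parse_error")
  }
  aa_ok <- function(a) {
    if (!a %in% AA3) {
      rlang::abort(paste0("unknown amino-acid code '", a, "' in '",
                          original, "'"),
                   class = "abca4_parse_error")
    }
    a
  }
  # frameshift: RefPosAltfs*N or RefPosfs
  m <- regmatches(token,
                  regexec("^([A-Z][a-z]{2})(\\d+)([A-Z][a-z]{2})?fs(\\*(\\d+))?$",
                          token))[[1]]
  if (length(m) > 0) {
    return(list(residue_index = as.integer(m[3]), ref_aa = aa_ok(m[2]),
                alt_aa = if (m[4] == "") NA_character_ else aa_ok(m[4]),
                kind = "frameshift",
                fs_ter = if (m[6] == "") NA_integer_ else as.integer(m[6])))
  }
  # synonymous: Ref Pos =
  m <- regmatches(token, regexec("^([A-Z][a-z]{2})(\\d+)=$", token))[[1]]
  if (length(m) > 0) {
    return(list(residue_index = as.integer(m[3]), ref_aa = aa_ok(m[2]),
                alt_aa = "=", kind = "synonymous", fs_ter = NA_integer_))
  }
  # substitution / nonsense: Ref Pos (Alt|Ter|*)
  m <- regmatches(token,
                  regexec("^([A-Z][a-z]{2})(\\d+)([A-Z][a-z]{2}|Ter|\\*)$",
                          token))[[1]]
  if (length(m) > 0) {
    alt <- m[4]
    if (alt %in% c("*", "Ter")) {
      return(list(residue_index = as.integer(m[3]), ref_aa = aa_ok(m[2]),
                  alt_aa = "Ter", kind = "nonsense", fs_ter = NA_integer_))
    }
    return(list(residue_index = as.integer(m[3]), ref_aa = aa_ok(m[2]),
                alt_aa = aa_ok(alt), kind = "substitution",
                fs_ter = NA_integer_))
  }
  bad()
}

#' Parse a protein change (HGVS subset)
#'
#' Supported forms: `p.(Cys205Phe)`, `p.(Leu1580*)`, `p.Thr1821Aspfs*6`,
#' synonymous `p.(Cys54=)`, and dual-effect records such as
#' `p.(Cys54=, Cys54Serfs*14)` whose first token is the primary effect.
#'
#' @param text A single string of the form `"p.(...)"` or `"p...."`.
#' @return A list of class `protein_change` with `residue_index`, `ref_aa`,
#'   `alt_aa` (`"Ter"` for stop, `"="` for synonymous), `kind`, and
#'   `secondary` (a further parsed record for dual-effect notation, or NULL).
#' @export
parse_protein <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (!startsWith(text, "p.")) {
    rlang::abort(paste0("cannot parse protein change: '", text, "'"),
                 class = "abca4_parse_error")
  }
  body <- sub("^p\\.", "", text)
  wrapped <- grepl("^\\(.*\\)$", body)
  if (wrapped) body <- sub("^\\((.*)\\)$", "\\1", body)
  tokens <- trimws(strsplit(body, ",")[[1]])
  if (length(tokens) == 0 || any(tokens == "")) {
    rlang::abort(paste0("cannot parse protein change: '", text, "'"),
                 class = "abca4_parse_error")
  }
  primary <- parse_protein_single(tokens[1], text)
  primary$secondary <- if (length(tokens) > 1) {
    parse_protein_single(tokens[2], text)
  } else {
    NULL
  }
  primary$wrapped <- wrapped
  structure(primary, class = "protein_change")
}

format_protein_single <- function(x) {
  if (x$kind == "synonymous") return(paste0(x$ref_aa, x$residue_index, "="))
  if (x$kind == "frameshift") {
    return(paste0(x$ref_aa, x$residue_index,
                  if (is.na(x$alt_aa)) "" else x$alt_aa, "fs",
                  if (is.na(x$fs_ter)) "" else paste0("*", x$fs_ter)))
  }
  if (x$kind == "nonsense") return(paste0(x$ref_aa, x$residue_index, "*"))
  paste0(x$ref_aa, x$residue_index, x$alt_aa)
}

#' Serialise a parsed protein change back to its HGVS string
#'
#' @param x A `protein_change` as returned by [parse_protein()].
#' @return A single string.
#' @export
format_protein <- function(x) {
  stopifnot(inherits(x, "protein_change"))
  body <- format_protein_single(x)
  if (!is.null(x$secondary)) {
    body <- paste0(body, ", ", format_protein_single(x$secondary))
  }
  if (isTRUE(x$wrapped)) paste0("p.(", body, ")") else paste0("p.", body)
}

#' Infer the consequence class of a parsed variant
#'
#' Intron offsets win over any annotated protein effect: a nonzero offset is
#' `splice_region` when |offset| is within `splice_region_window` and
#' `intronic` otherwise. Exonic changes are classified from the protein
#' effect (nonsense, frameshift, synonymous, missense); anything else falls
#' back to `other`.
#'
#' @param cdna A `cdna_change` (or `NULL`).
#' @param protein A `protein_change` (or `NULL`).
#' @param splice_region_window Maximum |intron offset| counted as
#'   splice-region; beyond it the change is deep intronic.
#' @return One of `"missense"`, `"intronic"`, `"splice_region"`,
#'   `"nonsense"`, `"frameshift"`, `"synonymous"`, `"other"`.
#' @export
infer_consequence <- function(cdna = NULL, protein = NULL,
                              splice_region_window = 20L) {
  if (!is.null(cdna) && cdna$intron_offset != 0L) {
    if (abs(cdna$intron_offset) <= splice_region_window) {
      return("splice_region")
    }
    return("intronic")
  }
  if (is.null(protein)) return("other")
  switch(protein$kind,
         nonsense = "nonsense",
         frameshift = "frameshift",
         synonymous = "synonymous",
         substitution = if (protein$ref_aa != protein$alt_aa) "missense"
                        else "other",
         "other")
}

#' Parse a passthrough evidence-code string
#'
#' Externally derived evidence arrives as semicolon-separated
#' `"CODE:strength"` tokens, e.g. `"PM3:very_strong;PP5:supporting"`. A bare
#' `"CODE"` token takes the code's canonical strength.
#'
#' @param text A single string (may be empty or NA for no codes).
#' @return An evidence tibble (see [evidence_code()]) with
#'   `source = "passthrough"`.
#' @export
parse_passthrough <- function(text) {
  if (length(text) != 1 || is.na(text) || !nzchar(trimws(text))) {
    return(empty_evidence())
  }
  tokens <- trimws(strsplit(text, ";")[[1]])
  tokens <- tokens[nzchar(tokens)]
  rows <- lapply(tokens, function(tok) {
    parts <- trimws(strsplit(tok, ":")[[1]])
    evidence_code(parts[1],
                  strength = if (length(parts) > 1) parts[2] else NULL,
                  source = "passthrough")
  })
  dplyr::bind_rows(rows)
}

#' Read a variant-annotation table from TSV
#'
#' One row per variant. Expected columns: `variant_id`, `cdna`, `protein`,
#' `revel`, `spliceai_max_delta`, `aux_splice_novel_site`, `gnomad_af`,
#' `gnomad_homozygotes`, `reported_in_patient`, `hypomorphic_flag`,
#' `localization`, `clinvar_same_residue` (a JSON array of objects with
#' `protein_change`, `classification`, `reported_in_abca4rd_patient`,
#' `revel`), and `passthrough_codes` (semicolon-separated `CODE:strength`
#' tokens). Missing values are coded as `"."`. A `consequence` column is
#' derived from the parsed nomenclature when absent.
#'
#' @param path Path to a TSV file.
#' @param splice_region_window Passed to [infer_consequence()].
#' @return An annotation tibble with list-columns `clinvar_same_residue`
#'   and `passthrough`.
#' @export
read_annotation_tsv <- function(path, splice_region_window = 20L) {
  raw <- readr::read_tsv(path, na = c(".", "NA", ""), show_col_types = FALSE,
                         progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  tbl <- tibble::tibble(
    variant_id = raw$variant_id,
    cdna = raw$cdna,
    protein = raw$protein,
    revel = as.numeric(raw$revel),
    spliceai_max_delta = as.numeric(raw$spliceai_max_delta),
    aux_splice_novel_site = as.logical(raw$aux_splice_novel_site),
    gnomad_af = as.numeric(raw$gnomad_af),
    gnomad_homozygotes = as.integer(raw$gnomad_homozygotes),
    reported_in_patient = as.logical(raw$reported_in_patient),
    hypomorphic_flag = as.logical(raw$hypomorphic_flag),
    localization = raw$localization,
    clinvar_same_residue = lapply(raw$clinvar_same_residue, function(js) {
      if (is.na(js)) return(tibble::tibble())
      tibble::as_tibble(jsonlite::fromJSON(js))
    }),
    passthrough = lapply(raw$passthrough_codes, parse_passthrough)
  )
  annotate_consequences(tbl, splice_region_window = splice_region_window)
}

#' Write a variant-annotation table to TSV
#'
#' Inverse of [read_annotation_tsv()]; list-columns are serialised back to
#' JSON / token form and missing values written as `"."`.
#'
#' @param annotations Annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(annotations, path) {
  out <- annotations
  out$clinvar_same_residue <- vapply(annotations$clinvar_same_residue,
    function(df) {
      if (is.null(df) || nrow(df) == 0) return(NA_character_)
      as.character(jsonlite::toJSON(df, auto_unbox = FALSE, digits = NA))
    }, character(1))
  out$passthrough_codes <- vapply(annotations$passthrough, function(ev) {
    if (is.null(ev) || nrow(ev) == 0) return(NA_character_)
    paste0(ev$code, ":", ev$strength, collapse = ";")
  }, character(1))
  out$passthrough <- NULL
  # JSON columns contain quotes but never tabs/newlines; write unquoted so
  # they parse back verbatim
  readr::write_tsv(out, path, na = ".", progress = FALSE,
                   quote = "none", escape = "none")
  invisible(path)
}

#' Fill in consequence classes by parsing nomenclature
#'
#' @param annotations Annotation tibble with `cdna` and `protein` columns.
#' @param splice_region_window Passed to [infer_consequence()].
#' @return The tibble with a `consequence` column (existing non-missing
#'   values are kept).
#' @export
annotate_consequences <- function(annotations, splice_region_window = 20L) {
  inferred <- vapply(seq_len(nrow(annotations)), function(i) {
    cd <- annotations$cdna[i]
    pr <- annotations$protein[i]
    infer_consequence(
      cdna = if (is.na(cd)) NULL else parse_cdna(cd),
      protein = if (is.na(pr)) NULL else parse_protein(pr),
      splice_region_window = splice_region_window
    )
  }, character(1))
  if (!"consequence" %in% names(annotations)) {
    annotations$consequence <- inferred
  } else {
    keep <- !is.na(annotations$consequence)
    annotations$consequence[!keep] <- inferred[!keep]
  }
  annotations
}
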