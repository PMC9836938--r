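# Syn61-style codon compression and translation under codon-reassignment
# schemes. The compressed strain lacks the TCG/TCA serine codons, the
# amber stop (TAG), their decoding tRNAs and release factor 1; compressed
# genes must not use these codons in frame, which frees TCG and TAG for
# reassignment to non-canonical monomers (TCA remains unassigned).

.STOP_CODONS <- c("TAA", "TGA")

.split_codons <- function(nucleotides) {
  nucleotides <- toupper(nucleotides)
  if (nchar(nucleotides) %% 3L != 0L) {
    stop("sequence length not divisible by 3 (frame error)")
  }
  if (grepl("[^ACGT]", nucleotides)) {
    stop("non-ACGT character in coding sequence")
  }
  if (nchar(nucleotides) == 0L) return(character(0))
  substring(nucleotides,
            seq(1L, nchar(nucleotides), 3L),
            seq(3L, nchar(nucleotides), 3L))
}

#' Syn61 recoding rules
#'
#' The synonymous (or stop-to-stop) codon substitutions used to compress
#' coding sequences for expression in Syn61-derived cells:
#' TCG -> AGC, TCA -> AGT, TAG -> TAA.
#'
#' @return Named character vector, `names` = source codons.
#' @export
syn61_rules <- function() {
  c(TCG = "AGC", TCA = "AGT", TAG = "TAA")
}

.check_rules <- function(rules) {
  stopifnot(is.character(rules), !is.null(names(rules)))
  if (anyDuplicated(names(rules))) stop("recoding rule domains overlap")
  gc <- Biostrings::GENETIC_CODE
  for (i in seq_along(rules)) {
    from <- names(rules)[i]; to <- rules[[i]]
    if (gc[[from]] != gc[[to]]) {
      stop("substitution ", from, "->", to, " is not synonymous")
    }
  }
  rules
}

#' Compress a coding sequence under recoding rules
#'
#' Frame-aware: only in-frame codons are substituted; out-of-frame
#' occurrences of a source codon are untouched. Translation under the
#' standard genetic code is unchanged (stop to stop counts as unchanged),
#' and compression is idempotent.
#'
#' @param cds DNA string over A/C/G/T, length divisible by 3.
#' @param rules Named codon-to-codon map; default [syn61_rules()].
#' @return The compressed DNA string.
#' @examples
#' compress("ATGTCGTCATAGTAA")  # "ATGAGCAGTTAATAA"
#' @export
compress <- function(cds, rules = syn61_rules()) {
  rules <- .check_rules(rules)
  codons <- .split_codons(cds)
  hit <- codons %in% names(rules)
  codons[hit] <- rules[codons[hit]]
  paste(codons, collapse = "")
}

#' List in-frame codons forbidden in Syn61-derived cells
#'
#' Reports every in-frame TCG, TCA or TAG with its 0-based codon index;
#' an empty report means the sequence is compression-compliant.
#'
#' @param cds DNA string over A/C/G/T, length divisible by 3.
#' @param forbidden Codons to flag; default `names(syn61_rules())`.
#' @return Data frame with columns `codon_index` (0-based) and `codon`.
#' @export
validate_syn61 <- function(cds, forbidden = names(syn61_rules())) {
  codons <- .split_codons(cds)
  idx <- which(codons %in% forbidden)
  data.frame(codon_index = idx - 1L, codon = codons[idx],
             stringsAsFactors = FALSE)
}

# --- reassignment schemes --------------------------------------------------

# The schemes used in the study. A decodes TCG, B decodes TAG; pair
# labels are metadata naming the synthetase/tRNA pair that decodes each
# codon. Schemes 1-3 assign two ncAAs (peptide macrocycles); 4-8 assign
# at least one alpha hydroxy acid (depsipeptide macrocycles).
.BUILTIN_SCHEMES <- list(
  list(scheme_id = "rs1", monomer_A = "1",  monomer_B = "3",
       pair_A = "MmPylRS/MmtRNAPyl(CGA)",
       pair_B = "AfTyrRS(pIF)/AftRNATyr(A01)(CUA)"),
  list(scheme_id = "rs2", monomer_A = "1",  monomer_B = "4",
       pair_A = "MmPylRS/MmtRNAPyl(CGA)",
       pair_B = "1R26PylRS(CbzK)/AlvtRNAdNPyl(8)(CUA)"),
  list(scheme_id = "rs3", monomer_A = "2",  monomer_B = "5",
       pair_A = "MmPylRS/MmtRNAPyl(CGA)",
       pair_B = "AfTyrRS(pAzF)/AftRNATyr(A01)(CUA)"),
  list(scheme_id = "rs4", monomer_A = "7",  monomer_B = "3",
       pair_A = "MmPylRS/MmtRNAPyl(CGA)",
       pair_B = "AfTyrRS(pIF)/AftRNATyr(A01)(CUA)"),
  list(scheme_id = "rs5", monomer_A = "7",  monomer_B = "12",
       pair_A = "MmPylRS/MmtRNAPyl(CGA)",
       pair_B = "1R26PylRS(CbzK)/AlvtRNAdNPyl(8)(CUA)"),
  list(scheme_id = "rs6", monomer_A = "8",  monomer_B = "5",
       pair_A = "MmPylRS/MmtRNAPyl(CGA)",
       pair_B = "AfTyrRS(pAzF)/AftRNATyr(A01)(CUA)"),
  list(scheme_id = "rs7", monomer_A = "14", monomer_B = "4",
       pair_A = "MmPylRS(PheOH_6)/MmtRNAPyl(CGA)",
       pair_B = "1R26PylRS(CbzK)/AlvtRNAdNPyl(8)(CUA)"),
  list(scheme_id = "rs8", monomer_A = "16", monomer_B = "1",
       pair_A = "MmPylRS(ArOH)/MmtRNAPyl(CGA)",
       pair_B = "1R26PylRS/AlvtRNAdNPyl(8)(CUA)")
)

#' Construct or look up a codon reassignment scheme
#'
#' A scheme maps the liberated codons to monomers: `monomer_A` is
#' incorporated in response to TCG and `monomer_B` in response to TAG
#' (TCA has no assignment). The eight schemes used in the study ship as
#' `"rs1"` .. `"rs8"`; custom schemes are built by giving `monomer_A`
#' and `monomer_B` explicitly. `monomer_B = "*"` declares a degenerate
#' scheme in which TAG behaves as a stop codon.
#'
#' @param scheme_id Built-in id (`"rs1"`..`"rs8"`) or a label for a
#'   custom scheme.
#' @param monomer_A,monomer_B Registry monomer ids (custom schemes only).
#' @param pair_A,pair_B Synthetase/tRNA pair labels (metadata).
#' @param registry A [monomer_registry()] used to validate monomer ids.
#' @return A list of class `reassignment_scheme`.
#' @examples
#' reassignment_scheme("rs6")
#' @export
reassignment_scheme <- function(scheme_id, monomer_A = NULL, monomer_B = NULL,
                                pair_A = NA_character_, pair_B = NA_character_,
                                registry = monomer_registry()) {
  if (is.null(monomer_A) && is.null(monomer_B)) {
    hit <- Filter(function(s) s$scheme_id == scheme_id, .BUILTIN_SCHEMES)
    if (!length(hit)) stop("unknown built-in scheme: ", scheme_id)
    s <- hit[[1]]
  } else {
    if (is.null(monomer_A) || is.null(monomer_B)) {
      stop("custom schemes need both monomer_A and monomer_B")
    }
    s <- list(scheme_id = scheme_id, monomer_A = monomer_A,
              monomer_B = monomer_B, pair_A = pair_A, pair_B = pair_B)
  }
  if (identical(s$monomer_A, s$monomer_B)) {
    stop("monomer_A and monomer_B must differ")
  }
  .lookup_monomer(setdiff(c(s$monomer_A, s$monomer_B), "*"), registry)
  structure(s, class = "reassignment_scheme")
}

#' All built-in reassignment schemes
#'
#' @return Data frame, one row per scheme.
#' @export
builtin_schemes <- function() {
  do.call(rbind, lapply(.BUILTIN_SCHEMES, as.data.frame))
}

#' @export
print.reassignment_scheme <- function(x, ...) {
  cat("<reassignment_scheme> ", x$scheme_id,
      ": TCG -> ", x$monomer_A, " (", x$pair_A, "), TAG -> ",
      x$monomer_B, " (", x$pair_B, ")\n", sep = "")
  invisible(x)
}

#' Translate a coding sequence under a reassignment scheme
#'
#' Standard-genetic-code translation except that TCG yields the scheme's
#' monomer A and TAG its monomer B. In-frame TCA is a hard error (its
#' decoding tRNA is deleted; silent acceptance would fabricate biology),
#' as is an internal TAA/TGA. A terminal TAA/TGA stop is dropped.
#'
#' @param cds DNA string, length divisible by 3.
#' @param scheme A [reassignment_scheme()].
#' @param registry A [monomer_registry()].
#' @return Character vector of monomer ids in sequence order.
#' @examples
#' translate_reassigned("CTGTCGTAG", reassignment_scheme("rs3"))
#' @export
translate_reassigned <- function(cds, scheme,
                                 registry = monomer_registry()) {
  stopifnot(inherits(scheme, "reassignment_scheme"))
  codons <- .split_codons(cds)
  n <- length(codons)
  out <- character(0)
  for (i in seq_len(n)) {
    codon <- codons[i]
    monomer <- if (codon == "TCG") scheme$monomer_A
      else if (codon == "TAG") scheme$monomer_B
      else if (codon == "TCA") stop("unassigned codon TCA at codon index ",
                                    i - 1L, " (no decoding tRNA)")
      else Biostrings::GENETIC_CODE[[codon]]
    if (monomer == "*") {
      if (i < n) stop("premature stop codon ", codon, " at codon index ",
                      i - 1L)
      break
    }
    out <- c(out, monomer)
  }
  .lookup_monomer(unique(out), registry)
  out
}
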