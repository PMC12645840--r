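#' @importFrom Biostrings DNAStringSet reverseComplement readDNAStringSet
#'   subseq
NULL

.ACGT <- c("A", "C", "G", "T")
.IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

.complement <- c(A = "T", C = "G", G = "C", T = "A")

.revcomp <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  if (any(ok)) {
    out[ok] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[ok]))
    )
  }
  out
}

.is_acgt_string <- function(x) {
  !is.na(x) & nzchar(x) & !grepl("[^ACGT]", x)
}

#' Categorize a variant from its REF and ALT alleles
#'
#' Applies the 9-way categorization used throughout the package:
#' `no_variant` (ALT absent, `"."`, or equal to REF), `snv`, `mnv` (equal
#' lengths > 1), `insertion` (ALT extends REF by a suffix, VCF anchor-base
#' style), `deletion` (REF extends ALT), `complex` (different lengths and
#' compositions), `sv` (symbolic `<...>` or breakend ALT), `ambiguous`
#' (IUPAC ambiguity code in ALT), and `uncategorized` (anything else, e.g.
#' a non-ACGT REF).  Alleles are parsed case-insensitively.  Insertions and
#' deletions are expected left-aligned with an anchor base; non-anchored
#' length changes fall through to `complex`.
#'
#' @param ref character vector of reference alleles (non-empty).
#' @param alt character vector of alternate alleles; `NA` or `"."` means no
#'   variant; symbolic alleles (`<DEL>`, breakends) are allowed.
#' @return character vector of variation types.
#' @examples
#' classifyVariant(c("A", "AT", "A", "ATT"), c("G", "GC", "ATT", "A"))
#' @export
classifyVariant <- function(ref, alt) {
  if (length(ref) == 0L) return(character(0))
  n <- max(length(ref), length(alt))
  ref <- rep_len(toupper(as.character(ref)), n)
  alt <- rep_len(toupper(as.character(alt)), n)
  if (any(is.na(ref) | !nzchar(ref))) {
    stop("empty REF allele is not allowed")
  }
  out <- rep("uncategorized", n)

  no_var <- is.na(alt) | alt == "." | alt == ref | !nzchar(alt)
  sv <- !no_var & (grepl("^<.*>$", alt) | grepl("[][]", alt))
  ambig <- !no_var & !sv &
    grepl(paste0("[", paste(.IUPAC_AMBIG, collapse = ""), "]"), alt)
  out[no_var] <- "no_variant"
  out[sv] <- "sv"
  out[ambig] <- "ambiguous"

  todo <- !(no_var | sv | ambig)
  ref_ok <- .is_acgt_string(ref)
  alt_ok <- .is_acgt_string(alt)
  seqs <- todo & ref_ok & alt_ok
  nr <- nchar(ref)
  na_ <- nchar(alt)

  out[seqs & nr == 1L & na_ == 1L] <- "snv"
  out[seqs & nr > 1L & nr == na_] <- "mnv"
  ins <- seqs & na_ > nr & substr(alt, 1L, nr) == ref
  del <- seqs & nr > na_ & substr(ref, 1L, na_) == alt
  out[ins] <- "insertion"
  out[del] <- "deletion"
  cpx <- seqs & nr != na_ & !ins & !del
  out[cpx] <- "complex"
  # remaining: non-ACGT ref with sequence alt, etc. -> uncategorized
  out
}

#' Trinucleotide context of sites against a reference
#'
#' Returns the uppercase 3-mer centered on `start` for each (contig, start)
#' pair.  The context is undefined (`NA`) at the first or last base of a
#' contig and whenever any of the three bases is not A/C/G/T, so no sequence
#' is ever fabricated at contig edges or around masked bases.
#'
#' @param contig character vector of reference-sequence names.
#' @param start integer vector of 1-based positions.
#' @param reference a [Biostrings::DNAStringSet] or path to a FASTA file.
#' @return character vector of 3-mers (or `NA` where undefined).
#' @export
trinucleotideContext <- function(contig, start, reference) {
  reference <- .as_reference(reference)
  contig <- as.character(contig)
  start <- as.integer(start)
  missing_ctg <- setdiff(unique(contig), names(reference))
  if (length(missing_ctg)) {
    stop("contigs absent from reference: ",
         paste(missing_ctg, collapse = ", "))
  }
  lens <- Biostrings::width(reference)[match(contig, names(reference))]
  out <- rep(NA_character_, length(contig))
  ok <- !is.na(start) & start > 1L & start < lens
  if (any(ok)) {
    ctx <- as.character(Biostrings::subseq(
      reference[contig[ok]], start = start[ok] - 1L, width = 3L))
    ctx <- toupper(ctx)
    ctx[grepl("[^ACGT]", ctx)] <- NA_character_
    out[ok] <- ctx
  }
  out
}

.as_reference <- function(reference) {
  if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    # FASTA descriptions: keep the first word as the contig name
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  if (!methods::is(reference, "DNAStringSet")) {
    stop("reference must be a DNAStringSet or a FASTA path")
  }
  reference
}

#' Pyrimidine-strand subtype labels for SNVs
#'
#' Computes the subtype labels of SNVs at the four resolutions used for
#' spectra: 12-base keeps the strand as observed (`"G>T"`); 6-base
#' reverse-complements purine-reference records onto the pyrimidine strand
#' (`"G>T"` becomes `"C>A"`); 96-base is the 6-base subtype within its
#' pyrimidine-strand trinucleotide context, formatted `"G[C>A]T"`; 192-base
#' keeps the strand within the observed context (`"A[G>T]C"`).  Context-
#' dependent labels are `NA` when the context is undefined.
#'
#' @param ref,alt single-base character vectors (SNVs only).
#' @param context character vector of 3-mer contexts centered on the site
#'   (may be `NA`).
#' @return `data.frame` with columns `normalized_ref`, `normalized_alt`,
#'   `subtype` (12-base), `normalized_subtype` (6-base),
#'   `normalized_context`, `context_with_mutation` (192-base) and
#'   `normalized_context_with_mutation` (96-base).
#' @examples
#' normalizeSubtype("G", "T", "AGC")   # 6-base C>A, 96-base G[C>A]T
#' @export
normalizeSubtype <- function(ref, alt, context = NA_character_) {
  n <- max(length(ref), length(alt))
  ref <- rep_len(toupper(as.character(ref)), n)
  alt <- rep_len(toupper(as.character(alt)), n)
  context <- rep_len(toupper(as.character(context)), n)
  if (any(classifyVariant(ref, alt) != "snv")) {
    stop("normalizeSubtype() is defined for SNV records only")
  }
  context[!.is_acgt_string(context) | nchar(context) != 3L] <- NA_character_
  mid_ok <- is.na(context) | substr(context, 2L, 2L) == ref
  if (any(!mid_ok)) {
    stop("context middle base does not match the reference allele")
  }
  purine <- ref %in% c("A", "G")
  nref <- ifelse(purine, .complement[ref], ref)
  nalt <- ifelse(purine, .complement[alt], alt)
  nctx <- context
  nctx[purine] <- .revcomp(context[purine])

  subtype <- paste0(ref, ">", alt)
  nsub <- paste0(nref, ">", nalt)
  ctx192 <- ifelse(is.na(context), NA_character_,
    paste0(substr(context, 1, 1), "[", subtype, "]", substr(context, 3, 3)))
  ctx96 <- ifelse(is.na(nctx), NA_character_,
    paste0(substr(nctx, 1, 1), "[", nsub, "]", substr(nctx, 3, 3)))
  data.frame(
    normalized_ref = unname(nref), normalized_alt = unname(nalt),
    subtype = subtype, normalized_subtype = nsub,
    normalized_context = nctx,
    context_with_mutation = ctx192,
    normalized_context_with_mutation = ctx96,
    stringsAsFactors = FALSE
  )
}

#' Canonical 96-channel SBS context labels
#'
#' The 96 single-base-substitution channels in COSMIC order: substitutions
#' C>A, C>G, C>T, T>A, T>C, T>G, each within the 16 trinucleotide contexts
#' ordered alphabetically by 5' then 3' flank.
#'
#' @return character vector of 96 labels such as `"A[C>A]A"`.
#' @export
sbsChannels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- character(0)
  for (s in subs) {
    r <- substr(s, 1, 1)
    for (f5 in .ACGT) for (f3 in .ACGT) {
      out <- c(out, paste0(f5, "[", s, "]", f3))
    }
  }
  out
}

#' The six pyrimidine-strand SNV subtypes
#' @return character vector `c("C>A","C>G","C>T","T>A","T>C","T>G")`.
#' @export
snvSubtypes6 <- function() c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The twelve stranded SNV subtypes
#' @return character vector of all `ref>alt` pairs over A/C/G/T.
#' @export
snvSubtypes12 <- function() {
  out <- character(0)
  for (r in .ACGT) for (a in setdiff(.ACGT, r)) out <- c(out, paste0(r, ">", a))
  out
}
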