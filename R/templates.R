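## Sequence utilities and the lepidopteran segment templates shared by the
## generator and the annotator.

DNA_BASES <- c("A", "C", "G", "T")

## invertebrate mitochondrial code (translation table 5): TAA/TAG are the only
## stops; AGA/AGG encode serine.
MITO_STOPS <- c("TAA", "TAG")

## legitimate mitochondrial start codons: ATN, GTG, TTG, GTT
LEGIT_STARTS <- c("ATA", "ATC", "ATG", "ATT", "GTG", "TTG", "GTT")

## canonical overlap (nt) of atp6 with the 3' end of atp8
ATP6_OVERLAP <- 7L

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

## base-set -> IUPAC code, keyed by sorted concatenation of the set
IUPAC_CODE <- local({
  m <- vapply(IUPAC_SETS, function(s) paste(sort(s), collapse = ""), "")
  setNames(names(m), m)
})

#' Reverse complement of a DNA string
#'
#' Plain-character convenience wrapper used throughout the package; IUPAC
#' ambiguity codes are complemented as well.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse-complemented strings.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## split a DNA string into a character vector of single bases
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

## codons of a string (truncated tail dropped)
codons_of <- function(x) {
  n <- nchar(x) %/% 3L
  if (n == 0L) return(character(0))
  substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

is_stop_codon <- function(codon) codon %in% MITO_STOPS

#' Translate a coding sequence with the invertebrate mitochondrial code
#'
#' Truncated terminal codons are completed to TAA (polyadenylation) before
#' translation when `complete_trunc` is `TRUE`.  Ambiguous codons translate to
#' `X` and never form a stop.
#'
#' @param x DNA string (length divisible by 3 unless a truncated stop is
#'   being completed).
#' @param complete_trunc complete a trailing `T`/`TA` to `TAA` first.
#' @return single amino-acid string.
#' @export
translate_mito <- function(x, complete_trunc = TRUE) {
  if (complete_trunc) x <- complete_truncated_stop(x)
  if (nchar(x) %% 3L != 0L)
    stop("coding sequence length not divisible by 3")
  aa <- Biostrings::translate(Biostrings::DNAStringSet(x),
    genetic.code = Biostrings::getGeneticCode("5"),
    if.fuzzy.codon = "X")
  as.character(aa)
}

#' Complete a truncated stop codon by polyadenylation
#'
#' A trailing `T` or `TA` left by transcript processing is padded with `A`s to
#' a full `TAA` stop.
#'
#' @param x DNA string.
#' @return DNA string whose length is divisible by 3.
#' @export
complete_truncated_stop <- function(x) {
  r <- nchar(x) %% 3L
  if (r == 1L) paste0(x, "AA") else if (r == 2L) paste0(x, "A") else x
}

## can two bases pair in a stem?  Watson-Crick plus the G.T wobble.
bases_pair <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
  (a == "C" & b == "G") | (a == "G" & b == "C") |
  (a == "G" & b == "T") | (a == "T" & b == "G")
}

#' IUPAC consensus of equal-length sequences
#'
#' Per position, the smallest IUPAC code covering all observed bases.
#'
#' @param seqs character vector of equal-length DNA strings.
#' @return single IUPAC string, or `NA` if lengths differ or input empty.
#' @export
iupac_consensus <- function(seqs) {
  if (length(seqs) == 0L) return(NA_character_)
  n <- unique(nchar(seqs))
  if (length(n) != 1L) return(NA_character_)
  mat <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  code <- vapply(seq_len(n), function(j) {
    obs <- sort(unique(unlist(IUPAC_SETS[mat[, j]], use.names = FALSE)))
    IUPAC_CODE[[paste(obs, collapse = "")]]
  }, "")
  paste(code, collapse = "")
}

#' Match DNA strings against an IUPAC consensus
#'
#' @param seqs character vector of DNA strings.
#' @param consensus IUPAC string.
#' @return logical vector; sequences of a different length never match.
#' @export
iupac_match <- function(seqs, consensus) {
  n <- nchar(consensus)
  cs <- seq_chars(consensus)
  vapply(seqs, function(s) {
    if (is.na(s) || nchar(s) != n) return(FALSE)
    b <- seq_chars(toupper(s))
    all(vapply(seq_len(n), function(j) b[j] %in% IUPAC_SETS[[cs[j]]], NA))
  }, NA, USE.NAMES = FALSE)
}

## number of degenerate (non-ACGT) positions of an IUPAC string
iupac_degeneracy <- function(consensus) {
  sum(!seq_chars(consensus) %in% DNA_BASES)
}

## --------------------------------------------------------------------------
## tRNA cloverleaf template geometry.  Arm sizes follow the canonical insect
## mitochondrial cloverleaf: 7 bp acceptor stem, 4 bp D stem with a 7 nt DHU
## loop, 5 bp anticodon stem with a 7 nt loop (anticodon centered), 5 bp T
## stem with a 7 nt TPsiC loop.
CLOVERLEAF_GEOMETRY <- list(
  acc = 7L, dstem = 4L, dloop = 7L, acstem = 5L, acloop = 7L,
  tstem = 5L, tloop = 7L)

trna_template_length <- function() {
  g <- CLOVERLEAF_GEOMETRY
  2L * (g$acc + g$dstem + g$acstem + g$tstem) + g$dloop + g$acloop + g$tloop
}

#' Canonical anticodons of the seven sequenced mitochondrial tRNAs
#'
#' Named character vector (gene orientation) used both by the generator
#' and by the anticodon-anchored cloverleaf search.
#' @export
TRNA_ANTICODONS <- c(
  trnL2 = "TAA", trnK = "CTT", trnD = "GTC", trnH = "GTG",
  trnS2 = "TGA", trnL1 = "TAG", trnV = "TAC")

## --------------------------------------------------------------------------
## The three sequenced mitogenome segments in the lepidopteran gene order.
## `len` is the nominal feature length used to seed the generator and to
## center the annotation search windows; PCG lengths include the stop (or the
## truncated stop remainder).  `trunc` marks protein genes that end on a
## truncated stop abutting the next gene.

segment_templates <- function() {
  tl <- trna_template_length()
  list(
    cox1_cox3 = list(
      segment_id = "cox1_cox3",
      features = data.frame(
        feature = c("cox1", "trnL2", "cox2", "trnK", "trnD", "atp8",
                    "atp6", "cox3"),
        type = c("PCG", "tRNA", "PCG", "tRNA", "tRNA", "PCG", "PCG", "PCG"),
        strand = rep("+", 8L),
        len = c(1536L, tl, 676L, tl, tl, 162L, 678L, 786L),
        trunc = c("", "", "T", "", "", "", "", ""),
        stringsAsFactors = FALSE)),
    nad5_nad4 = list(
      segment_id = "nad5_nad4",
      features = data.frame(
        feature = c("nad5", "trnH", "nad4"),
        type = c("PCG", "tRNA", "PCG"),
        strand = c("-", "-", "-"),
        len = c(1734L, tl, 1337L),
        trunc = c("", "", "TA"),
        stringsAsFactors = FALSE)),
    cob_CR = list(
      segment_id = "cob_CR",
      features = data.frame(
        feature = c("cob", "trnS2", "nad1", "trnL1", "rrnL", "trnV",
                    "rrnS", "AT_rich"),
        type = c("PCG", "tRNA", "PCG", "tRNA", "rRNA", "tRNA", "rRNA",
                 "control_region"),
        strand = c("+", "+", "-", "-", "-", "-", "-", "+"),
        len = c(1146L, tl, 936L, tl, 1350L, tl, 780L, 350L),
        trunc = rep("", 8L),
        stringsAsFactors = FALSE))
  )
}

## spacer loci always carried in the root genome (taxon-ubiquitous)
ROOT_SPACERS <- list(`trnS2-nad1` = 24L)

## gene-direction neighbours used by the truncated-stop rule are derived from
## the template at annotation time, not hard coded.

segment_of_gene <- function(gene) {
  for (tpl in segment_templates())
    if (gene %in% tpl$features$feature) return(tpl$segment_id)
  NA_character_
}

## round half up at `digits` decimals (R's round() is banker's rounding);
## the epsilon guards exact decimal ties against binary representation
round_half_up <- function(x, digits = 3L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
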