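## Multiple alignments: codon-aware protein-backbone alignment of coding
## genes, structure-guided RNA alignment with a deterministic stem-gap
## correction, and named concatenations with partition schemes.  The
## progressive alignments themselves are delegated to MAFFT.

#' Align sequences with MAFFT
#'
#' Thin deterministic wrapper around the `mafft` executable (`--auto`).
#'
#' @param seqs named character vector (DNA or protein).
#' @param type `"nucleotide"` or `"protein"`.
#' @return named character vector of aligned sequences, input order.
#' @export
mafft_align <- function(seqs, type = c("nucleotide", "protein")) {
  type <- match.arg(type)
  if (length(seqs) == 1L) return(seqs)
  if (Sys.which("mafft") == "")
    stop("the 'mafft' executable is required but was not found on PATH")
  fin <- tempfile(fileext = ".fa"); fout <- tempfile(fileext = ".fa")
  on.exit(unlink(c(fin, fout)))
  writeLines(paste0(">", names(seqs), "\n", seqs), fin)
  args <- c("--auto", "--quiet",
            if (type == "protein") "--amino" else "--nuc", fin)
  status <- system2("mafft", args, stdout = fout, stderr = FALSE)
  if (status != 0L) stop("mafft failed with status ", status)
  x <- Biostrings::readBStringSet(fout)
  out <- toupper(setNames(as.character(x), names(x)))
  out[names(seqs)]
}

#' Codon-aware alignment through a translated backbone
#'
#' Coding sequences are completed at truncated stops (polyadenylation to
#' TAA), stripped of their terminal stop codon, translated with the
#' invertebrate mitochondrial code, aligned at the protein level, and
#' back-translated so that every amino-acid column corresponds to one
#' intact codon column triple.
#'
#' @param cds named character vector of coding sequences (length divisible
#'   by 3 after truncated-stop completion).
#' @return list of class `codon_alignment`: `nt` (nucleotide alignment),
#'   `protein` (the backbone), both named character vectors.
#' @export
codon_align <- function(cds) {
  cds <- vapply(cds, complete_truncated_stop, "", USE.NAMES = TRUE)
  bad <- nchar(cds) %% 3L != 0L
  if (any(bad))
    stop("CDS length not divisible by 3 after completion: ",
         paste(names(cds)[bad], collapse = ", "))
  ## drop the terminal stop codon so frames stay comparable
  nm <- names(cds)
  last <- substring(cds, nchar(cds) - 2L)
  cds <- ifelse(last %in% MITO_STOPS, substring(cds, 1L, nchar(cds) - 3L),
                cds)
  names(cds) <- nm
  aa <- vapply(cds, translate_mito, "", USE.NAMES = TRUE)
  internal_stop <- grepl("\\*", aa)
  if (any(internal_stop))
    stop("internal stop codon in: ",
         paste(names(aa)[internal_stop], collapse = ", "))
  aligned_aa <- mafft_align(aa, type = "protein")
  nt <- vapply(names(aligned_aa), function(tx) {
    cods <- codons_of(cds[[tx]])
    cols <- seq_chars(aligned_aa[[tx]])
    out <- character(length(cols))
    k <- 0L
    for (i in seq_along(cols)) {
      if (cols[i] == "-") out[i] <- "---"
      else { k <- k + 1L; out[i] <- cods[k] }
    }
    if (k != length(cods)) stop("back-translation length mismatch for ", tx)
    paste(out, collapse = "")
  }, "", USE.NAMES = TRUE)
  structure(list(nt = nt, protein = aligned_aa), class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon alignment: %d taxa, %d nt columns (%d aa)\n",
              length(x$nt), nchar(x$nt[1]), nchar(x$protein[1])))
  invisible(x)
}

## --------------------------------------------------------------------------
## Structure-guided RNA alignment

#' Per-base structure track of the canonical cloverleaf template
#'
#' @return character vector over the template length with values `"stem"`
#'   or `"loop"`.
#' @export
trna_template_track <- function() {
  g <- CLOVERLEAF_GEOMETRY
  rep(c("stem", "stem", "loop", "stem", "stem", "loop", "stem", "stem",
        "loop", "stem", "stem"),
      times = c(g$acc, g$dstem, g$dloop, g$dstem, 5L, g$acloop, 5L,
                g$tstem, g$tloop, g$tstem, g$acc))
}

## map a reference-sequence track onto alignment columns through the
## (gapped) reference row
track_to_columns <- function(aligned_ref, track) {
  cols <- seq_chars(aligned_ref)
  out <- character(length(cols))
  k <- 0L
  for (i in seq_along(cols)) {
    if (cols[i] == "-") out[i] <- "unpaired"
    else { k <- k + 1L; out[i] <- track[k] }
  }
  if (k != length(track))
    stop("structural error: template track length does not match reference")
  out
}

#' Deterministic stem-gap correction of an RNA alignment
#'
#' Operationalises the manual curation step of structure-guided alignment:
#' loop columns absorb length variation, so a gap run lying (partly) in
#' stem columns is relocated to the nearest position where it sits entirely
#' in non-stem columns, provided the realigned characters agree with the
#' column majorities (computed once on the input) at least as well as
#' before (an equal-or-better-score shift).  Rows and runs are processed
#' left to right; among acceptable placements the nearest wins, at equal
#' distance the higher-scoring one, then the rightward direction, so the
#' procedure is deterministic.
#'
#' @param aln named character vector of aligned sequences.
#' @param column_track per-column annotation (`"stem"`, `"loop"`,
#'   `"unpaired"`).
#' @return corrected alignment (named character vector).
#' @export
structure_correct <- function(aln, column_track) {
  m <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  if (ncol(m) != length(column_track))
    stop("structural error: track length != alignment length")
  ## column majority over non-gap characters, frozen for the whole pass
  majority <- apply(m, 2L, function(col) {
    col <- col[col != "-"]
    if (!length(col)) return("-")
    names(sort(table(col), decreasing = TRUE))[1]
  })
  stem <- column_track == "stem"
  n <- ncol(m)

  shift_delta <- function(row, i, j, k, dir) {
    ## score change from moving run [i, j] by k columns in direction dir
    len <- j - i + 1L
    if (dir > 0) { src <- (j + 1L):(j + k); dst <- src - len }
    else         { src <- (i - k):(i - 1L); dst <- src + len }
    ch <- row[src]
    if (any(ch == "-")) return(NA_real_)
    sum(ch == majority[dst]) - sum(ch == majority[src])
  }

  for (r in seq_len(nrow(m))) {
    row <- m[r, ]
    runs <- rle(row == "-")
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (q in which(runs$values)) {
      i <- starts[q]; j <- ends[q]
      if (!any(stem[i:j])) next
      len <- j - i + 1L
      best <- NULL
      for (k in seq_len(n)) {
        cand <- list()
        if (j + k <= n && !any(stem[(i + k):(j + k)]))
          cand <- c(cand, list(c(+1, k)))
        if (i - k >= 1L && !any(stem[(i - k):(j - k)]))
          cand <- c(cand, list(c(-1, k)))
        for (ck in cand) {
          d <- shift_delta(row, i, j, ck[2], ck[1])
          if (!is.na(d) && d >= 0 &&
              (is.null(best) || d > best$delta))
            best <- list(dir = ck[1], k = ck[2], delta = d)
        }
        if (!is.null(best)) break   # nearest acceptable placement wins
      }
      if (is.null(best)) next
      k <- best$k
      if (best$dir > 0) {
        moved <- row[(j + 1L):(j + k)]
        row[i:(i + k - 1L)] <- moved
        row[(i + k):(j + k)] <- "-"
      } else {
        moved <- row[(i - k):(i - 1L)]
        row[(j - k + 1L):j] <- moved
        row[(i - k):(j - k)] <- "-"
      }
    }
    m[r, ] <- row
  }
  setNames(apply(m, 1L, paste, collapse = ""), names(aln))
}

#' Structure-guided alignment of RNA orthologs
#'
#' Progressive nucleotide alignment followed by the deterministic stem-gap
#' correction of [structure_correct()], guided by the secondary-structure
#' track of a designated reference sequence.
#'
#' @param seqs named character vector of RNA gene sequences.
#' @param template list with `ref` (name of the reference sequence in
#'   `seqs`) and `track` (per-base `"stem"`/`"loop"`/`"unpaired"` labels of
#'   the ungapped reference).
#' @return list with `aln` (corrected alignment) and `column_track`.
#' @export
structure_align <- function(seqs, template) {
  if (!template$ref %in% names(seqs))
    stop("template reference ", template$ref, " not among the sequences")
  if (length(template$track) != nchar(seqs[[template$ref]]))
    stop("structural error: template track length != reference length")
  aln <- mafft_align(seqs, type = "nucleotide")
  ct <- track_to_columns(aln[[template$ref]], template$track)
  list(aln = structure_correct(aln, ct), column_track = ct)
}

## --------------------------------------------------------------------------
## Concatenation and partition schemes

#' Concatenate named alignments into a supermatrix with partitions
#'
#' Column-wise concatenation with one partition block per input alignment
#' and optional per-codon-position sub-blocks.  Taxa present in only some
#' blocks are dropped by default (mirroring the usual treatment of genes
#' unavailable for some taxa) or gap-filled on request.
#'
#' @param alignments named list of alignments (named character vectors).
#' @param set_name name of the concatenated set (e.g. `"mtpcg"`,
#'   `"aag13sp-set"`).
#' @param codon_blocks names of input alignments that should also be split
#'   into p1/p2/p3 sub-blocks in the partition scheme.
#' @param missing `"drop"` (keep only taxa present in every block) or
#'   `"gapfill"` (pad missing taxa with gaps).
#' @return list of class `concat_alignment`: `aln`, `scheme` (a
#'   `partition_scheme`: list of blocks with `label` and `cols`), `set_name`.
#' @export
concatenate <- function(alignments, set_name = "concat",
                        codon_blocks = character(0),
                        missing = c("drop", "gapfill")) {
  missing <- match.arg(missing)
  if (is.null(names(alignments)) || any(!nzchar(names(alignments))))
    stop("alignments must be named")
  for (a in alignments) {
    if (anyDuplicated(names(a))) stop("duplicate taxon in a block")
    if (length(unique(nchar(a))) != 1L) stop("ragged alignment block")
  }
  all_taxa <- unique(unlist(lapply(alignments, names)))
  in_all <- Reduce(intersect, lapply(alignments, names))
  taxa <- if (missing == "drop") in_all else all_taxa
  if (!length(taxa)) stop("no taxon present in every block")
  orphan <- setdiff(all_taxa, unlist(lapply(alignments, names)))
  if (length(orphan)) stop("taxon present in no block: ", orphan[1])

  pos <- 0L
  blocks <- list()
  rows <- setNames(rep("", length(taxa)), taxa)
  for (nm in names(alignments)) {
    a <- alignments[[nm]]
    w <- nchar(a[1])
    chunk <- vapply(taxa, function(tx) {
      if (tx %in% names(a)) a[[tx]] else strrep("-", w)
    }, "", USE.NAMES = TRUE)
    rows <- paste0(rows, chunk)
    names(rows) <- taxa
    cols <- (pos + 1L):(pos + w)
    if (nm %in% codon_blocks) {
      if (w %% 3L != 0L) stop("codon block ", nm, " length not divisible by 3")
      for (p in 1:3)
        blocks[[paste0(nm, "_p", p)]] <-
          list(label = paste0(nm, "_p", p), cols = cols[seq(p, w, by = 3L)])
    } else {
      blocks[[nm]] <- list(label = nm, cols = cols)
    }
    pos <- pos + w
  }
  scheme <- structure(list(name = set_name, blocks = blocks, n_cols = pos),
                      class = "partition_scheme")
  validate_partition_scheme(scheme)
  structure(list(aln = rows, scheme = scheme, set_name = set_name),
            class = "concat_alignment")
}

#' Validate a partition scheme (disjoint blocks covering all columns)
#'
#' @param scheme a `partition_scheme`.
#' @return invisibly `TRUE`; errors otherwise.
#' @export
validate_partition_scheme <- function(scheme) {
  cols <- unlist(lapply(scheme$blocks, `[[`, "cols"))
  if (anyDuplicated(cols)) stop("partition blocks overlap")
  if (!setequal(cols, seq_len(scheme$n_cols)))
    stop("partition blocks do not cover all columns")
  invisible(TRUE)
}

#' @export
print.concat_alignment <- function(x, ...) {
  cat(sprintf("%s: %d taxa x %d columns, %d partition blocks\n",
              x$set_name, length(x$aln), x$scheme$n_cols,
              length(x$scheme$blocks)))
  invisible(x)
}

#' Write a partition scheme in RAxML-style text
#'
#' Blocks with a codon step are written as `DNA, label = start-end\3`.
#'
#' @param scheme a `partition_scheme`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_raxml_partitions <- function(scheme, path) {
  lines <- vapply(scheme$blocks, function(b) {
    cols <- b$cols
    d <- unique(diff(cols))
    rng <- if (length(cols) == 1L) as.character(cols)
           else if (length(d) == 1L && d == 1L)
             sprintf("%d-%d", cols[1], cols[length(cols)])
           else if (length(d) == 1L && d == 3L)
             sprintf("%d-%d\\3", cols[1], cols[length(cols)])
           else paste(cols, collapse = ",")
    sprintf("DNA, %s = %s", b$label, rng)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write an alignment in relaxed PHYLIP format
#'
#' @param aln named character vector of aligned sequences.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_phylip <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(aln), nchar(aln[1])), con)
  writeLines(sprintf("%s  %s", names(aln), unname(aln)), con)
  invisible(path)
}

#' Remove gaps from aligned sequences
#'
#' @param aln named character vector of aligned sequences.
#' @return named character vector of ungapped sequences.
#' @export
degap <- function(aln) {
  setNames(gsub("-", "", aln, fixed = TRUE), names(aln))
}
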