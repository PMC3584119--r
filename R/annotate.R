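## Rule-based annotation of mitogenome segments: protein genes at the first
## legitimate in-frame start codon outside the upstream gene, 3' ends at the
## first in-frame stop or a truncated T/TA stop abutting the downstream gene,
## tRNAs as anticodon-anchored cloverleaf folds, rRNA limits taken from the
## flanking tRNAs, and intergenic spacers as the gaps between neighbours.
## Coordinates are 0-based half-open on the stored (plus) strand.

## oriented view of a segment: work on the reverse complement for minus
## strand features and map intervals back
orient_interval <- function(iv, L, strand) {
  if (is.null(iv) || strand == "+") return(iv)
  c(L - iv[2], L - iv[1])
}

#' Annotate one protein-coding gene
#'
#' The 5' end is placed at the first legitimate in-frame start codon (ATN,
#' GTG, TTG, GTT) in the search window that is not located within the
#' upstream same-strand feature; `atp6` may overlap the 3' end of `atp8` by
#' up to the canonical 7 nt.  The 3' end is at the first in-frame stop codon
#' (TAA/TAG, invertebrate mitochondrial code); when that stop lies within the
#' downstream same-strand feature, a truncated stop (`T` or `TA`) adjacent to
#' the downstream gene is assigned instead.  Minus-strand genes are processed
#' on the reverse complement and coordinates mapped back.
#'
#' @param sequence plus-strand segment sequence (character string).
#' @param gene gene name (only used for labelling and the atp6 exception).
#' @param search_window 0-based half-open interval (plus-strand coordinates)
#'   in which the start codon is searched.
#' @param strand `"+"` or `"-"`.
#' @param upstream_feature,downstream_feature gene-direction neighbours as
#'   annotation lists (or `NULL`); only their `start`/`end`/`strand` are
#'   used.
#' @param min_orf minimum ORF length (nt) for a candidate start to be
#'   accepted.
#' @return a `gene_annotation` list (gene, type, start, end, strand,
#'   start_codon, stop_codon, completeness), or `NULL` with a warning when
#'   no acceptable ORF exists.
#' @export
annotate_pcg <- function(sequence, gene, search_window, strand = "+",
                         upstream_feature = NULL, downstream_feature = NULL,
                         min_orf = 60L) {
  L <- nchar(sequence)
  s <- if (strand == "-") revcomp(sequence) else sequence
  win <- orient_interval(as.integer(search_window), L, strand)
  win[1] <- max(win[1], 0L); win[2] <- min(win[2], L)

  same_strand <- function(f) !is.null(f) && f$strand == strand
  up <- if (same_strand(upstream_feature))
    orient_interval(c(upstream_feature$start, upstream_feature$end), L, strand)
  down <- if (same_strand(downstream_feature))
    orient_interval(c(downstream_feature$start, downstream_feature$end), L,
                    strand)

  lo <- win[1]
  if (!is.null(up)) {
    slack <- if (identical(gene, "atp6")) ATP6_OVERLAP else 0L
    lo <- max(lo, up[2] - slack)
  }
  hi <- win[2]
  ch <- seq_chars(s)

  first_stop_from <- function(p) {
    # start position of the first in-frame stop codon at or after p
    q <- p
    while (q + 3L <= L) {
      if (paste(ch[(q + 1L):(q + 3L)], collapse = "") %in% MITO_STOPS)
        return(q)
      q <- q + 3L
    }
    NA_integer_
  }

  start <- NA_integer_; stop_at <- NA_integer_; start_codon <- NA_character_
  p <- lo
  while (p + 3L <= hi) {
    cod <- paste(ch[(p + 1L):(p + 3L)], collapse = "")
    if (cod %in% LEGIT_STARTS) {
      q <- first_stop_from(p + 3L)
      orf_len <- if (is.na(q)) L - p else q + 3L - p
      if (orf_len >= min_orf) {
        start <- p; stop_at <- q; start_codon <- cod
        break
      }
    }
    p <- p + 1L
  }
  if (is.na(start)) {
    warning("no ORF >= ", min_orf, " nt for ", gene, " in window")
    return(NULL)
  }

  completeness <- "complete"
  if (!is.null(down)) {
    d <- down[1]
    if (!is.na(stop_at) && stop_at + 3L <= d) {
      end <- stop_at + 3L
      stop_codon <- paste(ch[(stop_at + 1L):(stop_at + 3L)], collapse = "")
    } else {
      r <- (d - start) %% 3L
      end <- d
      stop_codon <- if (r == 1L) "T_trunc" else if (r == 2L) "TA_trunc"
                    else "none"
      if (r == 0L) completeness <- "partial3"
    }
  } else if (!is.na(stop_at)) {
    end <- stop_at + 3L
    stop_codon <- paste(ch[(stop_at + 1L):(stop_at + 3L)], collapse = "")
  } else {
    end <- start + 3L * ((L - start) %/% 3L)
    stop_codon <- "none"
    completeness <- "partial3"
  }

  iv <- orient_interval(c(start, end), L, strand)
  structure(list(gene = gene, type = "PCG", start = iv[1], end = iv[2],
                 strand = strand, start_codon = start_codon,
                 stop_codon = stop_codon, completeness = completeness),
            class = "gene_annotation")
}

## --------------------------------------------------------------------------
## Cloverleaf detection

## Stem scoring support: precompute the pairing indicator OK[i, j] (can bases
## i and j of the oriented window pair? Watson-Crick or G.T wobble) and its
## cumulative sums along anti-diagonals (i + j constant).  A stem pairing
## positions (i, j), (i+1, j-1), ..., (i+k-1, j-k+1) lies on one
## anti-diagonal, so its match count is a difference of two cumsum entries.
pairing_index <- function(states) {
  n <- length(states)
  comp <- c(4L, 3L, 2L, 1L)
  OK <- outer(comp[states], states, "==") |
    outer(states == 3L, states == 4L, "&") |
    outer(states == 4L, states == 3L, "&")
  diag_cum <- vector("list", 2L * n)
  diag_lo <- integer(2L * n)
  for (cc in 2:(2L * n)) {
    x <- max(1L, cc - n):min(n, cc - 1L)
    diag_lo[cc] <- x[1]
    diag_cum[[cc]] <- cumsum(OK[cbind(x, cc - x)])
  }
  list(n = n, diag_cum = diag_cum, diag_lo = diag_lo)
}

## matches of a k-long stem whose 5' arm starts at i (1-based) and whose 3'
## arm ends at j (so (i, j) is the outermost pair)
stem_matches <- function(px, i, j, k) {
  cc <- i + j
  S <- px$diag_cum[[cc]]
  lo <- px$diag_lo[cc]
  hi_idx <- i + k - 1L - lo + 1L
  lo_idx <- i - lo
  S[hi_idx] - if (lo_idx >= 1L) S[lo_idx] else 0
}

## score one candidate fold through the pairing index; O(1) per fold.
## score = paired positions - penalty * mismatching stem positions.
score_fold <- function(px, a, k1, l1, w, k2, l2, penalty) {
  g <- CLOVERLEAF_GEOMETRY
  acl <- 2L * w + 3L
  start <- a - (g$acc + k1 + l1 + k1 + 5L + w)  # 0-based fold start
  total <- 2L * (g$acc + k1 + 5L + k2) + l1 + acl + l2
  if (start < 0L || start + total > px$n) return(NULL)
  s1 <- start + 1L                               # 1-based
  acc_i <- s1
  d_i <- acc_i + g$acc
  dloop0 <- start + g$acc + k1                   # 0-based loop starts
  ac_i <- d_i + 2L * k1 + l1
  acloop0 <- start + g$acc + 2L * k1 + l1 + 5L
  t_i <- ac_i + 2L * 5L + acl
  tloop0 <- acloop0 + acl + 5L + k2
  end1 <- start + total                          # last 1-based index
  m <- stem_matches(px, acc_i, end1, g$acc) +
       stem_matches(px, d_i, d_i + 2L * k1 + l1 - 1L, k1) +
       stem_matches(px, ac_i, ac_i + 2L * 5L + acl - 1L, 5L) +
       stem_matches(px, t_i, t_i + 2L * k2 + l2 - 1L, k2)
  n_pairable <- g$acc + k1 + 5L + k2
  list(start = start, end = start + total,
       score = m - penalty * (n_pairable - m),
       n_match = m, n_pairable = n_pairable,
       dloop = c(dloop0, l1), acloop = c(acloop0, acl),
       tloop = c(tloop0, l2), geometry = c(k1, l1, w, k2, l2))
}

#' Find the best cloverleaf fold for an expected tRNA
#'
#' Anticodon-anchored search: every occurrence of an accepted anticodon in
#' the window seeds candidate folds over the allowed stem/loop geometries
#' (acceptor 7 bp, DHU stem 3-4 bp, anticodon stem 5 bp, T stem 4-5 bp,
#' loops 3-11 nt with the anticodon centered).  Folds are scored as the
#' number of paired stem positions minus a penalty per mismatching position
#' (G.T counts as a pair); the best fold is returned if its match count
#' reaches `min_frac` of the pairable positions.
#'
#' @param sequence plus-strand segment sequence.
#' @param name tRNA name.
#' @param anticodons accepted anticodon(s), gene orientation.
#' @param strand `"+"` or `"-"`.
#' @param window 0-based half-open plus-strand search interval.
#' @param penalty score penalty per mismatching stem position.
#' @param min_frac minimum fraction of pairable positions that must pair.
#' @param geometry optional fixed fold geometry `c(k1, l1, w, k2, l2)`
#'   (D-stem, DHU-loop, anticodon half-loop width, T-stem, TPsiC-loop
#'   sizes); used by comparative curation to constrain the search to the
#'   geometry of orthologous counterparts.
#' @param margin also report the score advantage of the best fold over the
#'   best fold with a different span.
#' @return list with `annotation` (a `gene_annotation`) and `cloverleaf`
#'   (loops with gene-orientation sequences and segment coordinates,
#'   anticodon, score, fold geometry), or `NULL` if no fold reaches the
#'   threshold.
#' @export
find_cloverleaf <- function(sequence, name, anticodons, strand = "+",
                            window = NULL, penalty = 1, min_frac = 0.8,
                            geometry = NULL, margin = FALSE) {
  L <- nchar(sequence)
  s <- if (strand == "-") revcomp(sequence) else sequence
  win <- if (is.null(window)) c(0L, L)
         else orient_interval(as.integer(window), L, strand)
  win[1] <- max(win[1], 0L); win[2] <- min(win[2], L)
  states <- dna_to_int(substr(s, win[1] + 1L, win[2]))
  offset <- win[1]

  anchors <- integer(0)
  for (ac in anticodons) {
    pat <- dna_to_int(ac)
    if (length(states) >= 3L) {
      hit <- which(states[seq_len(length(states) - 2L)] == pat[1] &
                   states[seq_len(length(states) - 2L) + 1L] == pat[2] &
                   states[seq_len(length(states) - 2L) + 2L] == pat[3])
      anchors <- c(anchors, hit - 1L)
    }
  }
  best <- NULL
  cand <- if (margin) list() else NULL
  if (length(anchors)) {
    px <- pairing_index(states)
    enumerate <- function(ac_min) {
      ## prefilter: an anchor/loop-width pair is only expanded when its
      ## anticodon stem (whose position depends on (a, w) alone) can pair
      ## at `ac_min` of 5 positions; most spurious anchors cannot
      aw <- list()
      for (a in anchors) for (w in 1:4) {
        i <- a - w - 5L + 1L
        j <- a + 3L + w + 5L
        if (i < 1L || j > px$n) next
        if (stem_matches(px, i, j, 5L) >= ac_min)
          aw[[length(aw) + 1L]] <- c(a, w)
      }
      if (!is.null(geometry)) {
        aw <- lapply(anchors, function(a) c(a, geometry[3]))
      }
      for (p_aw in aw) {
        a <- p_aw[1]; w <- p_aw[2]
        k1s <- if (is.null(geometry)) 3:4 else geometry[1]
        l1s <- if (is.null(geometry)) 3:11 else geometry[2]
        k2s <- if (is.null(geometry)) 4:5 else geometry[4]
        l2s <- if (is.null(geometry)) 3:11 else geometry[5]
        for (k1 in k1s) for (l1 in l1s) for (k2 in k2s)
          for (l2 in l2s) {
            f <- score_fold(px, a, k1, l1, w, k2, l2, penalty)
            if (is.null(f)) next
            if (margin)
              cand[[length(cand) + 1L]] <<- c(f$start, f$end, f$score)
            if (f$n_match < min_frac * f$n_pairable) next
            ## ties broken towards more paired positions, then towards
            ## the typical cloverleaf geometry (4 bp D stem, 5 bp T stem,
            ## 7 nt loops)
            f$canon <- abs(k1 - 4L) + abs(l1 - 7L) + abs(w - 2L) +
              abs(k2 - 5L) + abs(l2 - 7L)
            if (is.null(best) || f$score > best$score ||
                (f$score == best$score && f$n_match > best$n_match) ||
                (f$score == best$score && f$n_match == best$n_match &&
                 f$canon < best$canon))
              best <<- c(f, list(anchor = a))
          }
      }
    }
    enumerate(4L)
    ## a mutated anticodon stem can defeat the fast prefilter; retry with
    ## the weaker one before declaring the tRNA missing
    if (is.null(best)) {
      cand <- if (margin) list() else NULL
      enumerate(3L)
    }
  }
  if (is.null(best)) return(NULL)
  ## score advantage of the best fold over the best fold with a different
  ## span (used to certify that a template folds unambiguously)
  best_margin <- Inf
  if (margin && length(cand)) {
    cm <- do.call(rbind, cand)
    other <- cm[cm[, 1] != best$start | cm[, 2] != best$end, 3]
    if (length(other)) best_margin <- best$score - max(other)
  }

  sub_or <- function(iv) substr(s, offset + iv[1] + 1L, offset + iv[1] + iv[2])
  to_plus <- function(iv) {
    o <- c(offset + iv[1], offset + iv[1] + iv[2])
    if (strand == "-") c(L - o[2], L - o[1]) else o
  }
  ann_iv <- if (strand == "-") c(L - (offset + best$end),
                                 L - (offset + best$start))
            else c(offset + best$start, offset + best$end)
  anticodon_seq <- substr(s, offset + best$anchor + 1L,
                          offset + best$anchor + 3L)
  dl <- to_plus(best$dloop); tl <- to_plus(best$tloop); al <- to_plus(best$acloop)
  list(
    annotation = structure(list(
      gene = name, type = "tRNA", start = ann_iv[1], end = ann_iv[2],
      strand = strand, start_codon = NA_character_,
      stop_codon = NA_character_, completeness = "complete"),
      class = "gene_annotation"),
    cloverleaf = list(
      anticodon = anticodon_seq, score = best$score,
      n_match = best$n_match, n_pairable = best$n_pairable,
      geometry = best$geometry, margin = best_margin,
      loops = list(
        DHU = list(seq = sub_or(best$dloop), start = dl[1], end = dl[2]),
        anticodon_loop = list(seq = sub_or(best$acloop), start = al[1],
                              end = al[2]),
        TPsiC = list(seq = sub_or(best$tloop), start = tl[1], end = tl[2]))))
}

#' Find all expected tRNAs on a segment
#'
#' @param sequence plus-strand segment sequence.
#' @param expected data frame / list of lists with `name`, `anticodons`,
#'   `strand`, `window` (0-based half-open interval), and optional
#'   `geometry` / `min_frac` overrides.
#' @param min_frac default score threshold (see [find_cloverleaf()]).
#' @param ... passed to [find_cloverleaf()].
#' @return named list (per tRNA) of `find_cloverleaf()` results; missing
#'   tRNAs are reported with a warning and omitted.
#' @export
find_trnas <- function(sequence, expected, min_frac = 0.8, ...) {
  out <- list()
  for (e in expected) {
    hit <- find_cloverleaf(sequence, e$name, e$anticodons, e$strand,
                           e$window, geometry = e$geometry,
                           min_frac = e$min_frac %||% min_frac, ...)
    if (is.null(hit)) {
      warning("tRNA ", e$name, " not found above threshold")
      next
    }
    out[[e$name]] <- hit
  }
  out
}

#' Assign rRNA boundaries from flanking tRNAs
#'
#' `rrnL` is assumed to span the interval between `trnL1` and `trnV`; the
#' 3' end of `rrnS` abuts `trnV` and its 5' end is set by a configured
#' reference length.
#'
#' @param features named list of `gene_annotation`s (must contain `trnL1`
#'   and `trnV` for complete assignment).
#' @param segment_length length (nt) of the segment.
#' @param rrns_length reference length of `rrnS` used as the 5' anchor.
#' @return list of `gene_annotation`s for `rrnL` and `rrnS`; boundaries are
#'   flagged `partial5`/`partial3` (with a warning) when a flanking tRNA is
#'   missing.
#' @export
assign_rrna_boundaries <- function(features, segment_length,
                                   rrns_length = 780L) {
  trnL1 <- features[["trnL1"]]; trnV <- features[["trnV"]]
  mk <- function(gene, start, end, strand, completeness)
    structure(list(gene = gene, type = "rRNA", start = start, end = end,
                   strand = strand, start_codon = NA_character_,
                   stop_codon = NA_character_, completeness = completeness),
              class = "gene_annotation")
  out <- list()
  if (!is.null(trnL1) && !is.null(trnV)) {
    out$rrnL <- mk("rrnL", trnL1$end, trnV$start, trnV$strand, "complete")
  } else {
    warning("missing flanking tRNA; rrnL left partial")
    if (!is.null(trnL1))
      out$rrnL <- mk("rrnL", trnL1$end, segment_length, "-", "partial3")
  }
  if (!is.null(trnV)) {
    out$rrnS <- mk("rrnS", trnV$end,
                   min(trnV$end + rrns_length, segment_length),
                   trnV$strand, "complete")
  } else {
    warning("missing trnV; rrnS not assigned")
  }
  out
}

#' Extract intergenic spacers between adjacent features
#'
#' One record per adjacent feature pair, including zero-length records so
#' that presence/absence is retained.  Features must be non-overlapping
#' except for the canonical atp8/atp6 overlap and the small (few-nt)
#' overlaps that adjacent tRNAs commonly show in mitochondrial genomes;
#' such pairs get a zero-length spacer record.
#'
#' @param features list of `gene_annotation`s (any order; sorted by start).
#' @param sequence plus-strand segment sequence.
#' @param taxon optional taxon label carried into the output.
#' @return data frame with columns `taxon`, `locus`, `start`, `end`,
#'   `length`, `sequence`.
#' @export
extract_spacers <- function(features, sequence, taxon = NA_character_) {
  feats <- features[order(vapply(features, `[[`, 0L, "start"))]
  rows <- list()
  for (i in seq_len(length(feats) - 1L)) {
    a <- feats[[i]]; b <- feats[[i + 1L]]
    gap <- b$start - a$end
    if (gap < 0L) {
      allowed <- (a$gene == "atp8" && b$gene == "atp6" &&
                  -gap <= ATP6_OVERLAP) ||
                 ((a$type == "tRNA" || b$type == "tRNA") && -gap <= 5L)
      if (!allowed)
        stop("structural error: features ", a$gene, " and ", b$gene,
             " overlap by ", -gap, " nt")
      gap <- 0L
    }
    rows[[i]] <- data.frame(
      taxon = taxon, locus = paste0(a$gene, "-", b$gene),
      start = a$end, end = max(b$start, a$end), length = gap,
      sequence = if (gap > 0L) substr(sequence, a$end + 1L, b$start) else "",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

## --------------------------------------------------------------------------
## Template-driven segment annotation

## expected feature positions from the template nominal lengths
template_layout <- function(tpl) {
  f <- tpl$features
  f$exp_start <- cumsum(c(0L, f$len))[seq_len(nrow(f))]
  f$exp_end <- f$exp_start + f$len
  f
}

#' Annotate a full mitogenome segment from its gene-order template
#'
#' Two-pass template-driven annotation: tRNAs are located first by cloverleaf
#' search in windows centered on their template positions, then protein genes
#' are annotated between their gene-direction neighbours with the start/stop
#' boundary rules, rRNA limits are taken from `trnL1`/`trnV`, the control
#' region is the remainder after `rrnS`, and intergenic spacers are extracted
#' between all adjacent features.
#'
#' @param sequence plus-strand segment sequence.
#' @param segment_id one of `"cox1_cox3"`, `"nad5_nad4"`, `"cob_CR"`.
#' @param taxon taxon label carried into outputs.
#' @param slack half-width (nt) added around template windows.
#' @param min_orf_frac candidate ORFs must reach this fraction of the
#'   template gene length.
#' @param trna_geometry optional named list (per tRNA) of fixed fold
#'   geometries for comparative curation.
#' @param trna_window optional named list (per tRNA) of search-window
#'   overrides (0-based half-open intervals).
#' @param trna_min_frac optional named list (per tRNA) of score-threshold
#'   overrides.
#' @param ... passed to [find_cloverleaf()].
#' @return list with `features` (data frame, 0-based half-open),
#'   `spacers` (data frame) and `cloverleafs` (named list).
#' @export
annotate_segment <- function(sequence, segment_id, taxon = NA_character_,
                             slack = 150L, min_orf_frac = 0.5,
                             trna_geometry = list(), trna_window = list(),
                             trna_min_frac = list(), ...) {
  tpl <- segment_templates()[[segment_id]]
  if (is.null(tpl)) stop("unknown segment_id: ", segment_id)
  lay <- template_layout(tpl)
  L <- nchar(sequence)
  ann <- list()

  ## pass 1: tRNAs
  expected <- list()
  for (i in which(lay$type == "tRNA")) {
    expected[[length(expected) + 1L]] <- list(
      name = lay$feature[i],
      anticodons = TRNA_ANTICODONS[[lay$feature[i]]],
      strand = lay$strand[i],
      window = trna_window[[lay$feature[i]]] %||%
        c(max(0L, lay$exp_start[i] - slack),
          min(L, lay$exp_end[i] + slack)),
      geometry = trna_geometry[[lay$feature[i]]],
      min_frac = trna_min_frac[[lay$feature[i]]])
  }
  trnas <- find_trnas(sequence, expected, ...)
  for (nm in names(trnas)) ann[[nm]] <- trnas[[nm]]$annotation

  ## pass 2: protein genes, in template order
  for (i in which(lay$type == "PCG")) {
    gene <- lay$feature[i]
    strand <- lay$strand[i]
    neighbour <- function(j) if (j >= 1L && j <= nrow(lay))
      ann[[lay$feature[j]]] else NULL
    if (strand == "+") { upf <- neighbour(i - 1L); dnf <- neighbour(i + 1L) }
    else               { upf <- neighbour(i + 1L); dnf <- neighbour(i - 1L) }
    ov <- if (gene == "atp6") ATP6_OVERLAP else 0L
    ## when the template neighbour was not annotated (e.g. a tRNA below
    ## threshold), bound the window by the nearest annotated feature so
    ## the start search cannot wander into other genes
    ann_ends <- vapply(ann, `[[`, 0L, "end")
    ann_starts <- vapply(ann, `[[`, 0L, "start")
    win_lo <- if (!is.null(upf) && strand == "+") upf$end - ov
              else {
                lo <- max(0L, lay$exp_start[i] - slack)
                near <- ann_ends[ann_ends <= lay$exp_start[i] + 30L]
                if (length(near)) max(lo, max(near)) else lo
              }
    win_hi <- if (!is.null(upf) && strand == "-") upf$start
              else {
                hi <- min(L, lay$exp_end[i] + slack)
                near <- ann_starts[ann_starts >= lay$exp_end[i] - 30L]
                if (length(near)) min(hi, min(near)) else hi
              }
    ## the start is searched in the 5' part of the gene region
    if (strand == "+") win_hi <- min(L, win_lo + slack + 60L)
    else win_lo <- max(0L, win_hi - slack - 60L)
    a <- annotate_pcg(sequence, gene, c(win_lo, win_hi), strand,
                      upstream_feature = upf, downstream_feature = dnf,
                      min_orf = max(60L, floor(min_orf_frac * lay$len[i])))
    if (!is.null(a)) ann[[gene]] <- a
  }

  ## pass 3: rRNAs + control region
  if (any(lay$type == "rRNA")) {
    rr <- assign_rrna_boundaries(ann, L)
    ann <- c(ann, rr)
    if ("AT_rich" %in% lay$feature && !is.null(ann$rrnS)) {
      ann$AT_rich <- structure(list(
        gene = "AT_rich", type = "control_region", start = ann$rrnS$start,
        end = L, strand = "+", start_codon = NA_character_,
        stop_codon = NA_character_, completeness = "complete"),
        class = "gene_annotation")
      ann$AT_rich$start <- ann$rrnS$end
    }
  }

  ## order by template, keep found only
  ord <- lay$feature[lay$feature %in% names(ann)]
  ann <- ann[ord]
  feats <- do.call(rbind, lapply(ann, function(a) data.frame(
    taxon = taxon, segment = segment_id, feature = a$gene, type = a$type,
    start = a$start, end = a$end, strand = a$strand,
    start_codon = a$start_codon, stop_codon = a$stop_codon,
    completeness = a$completeness, stringsAsFactors = FALSE)))
  rownames(feats) <- NULL
  ## a conflicting feature call (reported upstream) should not void the
  ## rest of the segment; spacers are then unavailable for it
  spac <- tryCatch(extract_spacers(ann, sequence, taxon),
                   error = function(e) {
                     warning(conditionMessage(e))
                     NULL
                   })
  cl <- lapply(trnas, `[[`, "cloverleaf")
  list(features = feats, spacers = spac, cloverleafs = cl)
}

#' Annotate all taxa and segments of a set of mitogenome sequences
#'
#' @param segments taxon -> segment_id -> sequence nested list (as in a
#'   `truth_bundle`), or a FASTA file whose headers are `taxon|segment`.
#' @param curate comparative curation: after a first pass, tRNAs whose
#'   fold geometry deviates from the modal geometry of their orthologous
#'   counterparts are re-folded constrained to that modal geometry (kept
#'   only if the constrained fold still clears the score threshold).
#' @param ... passed to [annotate_segment()].
#' @return list with combined `features`, `spacers` data frames and a
#'   `cloverleafs` nested list (taxon -> tRNA).
#' @export
annotate_genomes <- function(segments, curate = TRUE, ...) {
  if (is.character(segments) && length(segments) == 1L &&
      file.exists(segments)) {
    seqs <- read_fasta(segments)
    parts <- strsplit(names(seqs), "|", fixed = TRUE)
    segments <- list()
    for (i in seq_along(seqs))
      segments[[parts[[i]][1]]][[parts[[i]][2]]] <- unname(seqs[i])
  }
  per_seg <- list()
  for (tx in names(segments))
    for (sid in names(segments[[tx]]))
      per_seg[[paste0(tx, "|", sid)]] <-
        annotate_segment(segments[[tx]][[sid]], sid, taxon = tx, ...)

  if (curate && length(segments) > 2L) {
    ## modal fold geometry per tRNA across taxa
    all_geom <- list()
    for (a in per_seg)
      for (tr in names(a$cloverleafs))
        all_geom[[tr]] <- c(all_geom[[tr]],
                            list(a$cloverleafs[[tr]]$geometry))
    modal <- lapply(all_geom, function(gl) {
      keys <- vapply(gl, paste, "", collapse = "-")
      as.integer(strsplit(names(sort(table(keys),
                                     decreasing = TRUE))[1], "-")[[1]])
    })
    n_taxa <- length(segments)
    found_count <- vapply(all_geom, length, 0L)
    ## median position and length per tRNA across taxa
    pos_stats <- list()
    for (a in per_seg) {
      tr_rows <- a$features[a$features$type == "tRNA", ]
      for (i in seq_len(nrow(tr_rows)))
        pos_stats[[tr_rows$feature[i]]] <-
          rbind(pos_stats[[tr_rows$feature[i]]],
                c(tr_rows$start[i], tr_rows$end[i] - tr_rows$start[i]))
    }
    med <- lapply(pos_stats, function(m)
      c(start = median(m[, 1]), len = median(m[, 2])))
    tpl_all <- segment_templates()

    for (key in names(per_seg)) {
      a <- per_seg[[key]]
      parts <- strsplit(key, "|", fixed = TRUE)[[1]]
      seq_p <- segments[[parts[1]]][[parts[2]]]
      tplf <- tpl_all[[parts[2]]]$features
      expected_tr <- tplf$feature[tplf$type == "tRNA"]
      ## per-tRNA candidate corrections, each pre-validated by a direct
      ## constrained fold search before the segment is re-annotated
      geoms <- list(); wins <- list(); fracs <- list()
      for (tr in expected_tr) {
        strand_tr <- tplf$strand[tplf$feature == tr]
        st <- a$features$start[a$features$feature == tr]
        found_here <- length(st) == 1L
        if (found_here) {
          g <- as.integer(a$cloverleafs[[tr]]$geometry)
          dev_geom <- !identical(g, modal[[tr]])
          ## a positionally deviant but confidently paired fold is
          ## trusted (genuine shifts, e.g. lineage-specific spacers);
          ## only marginal folds defer to the orthologous position
          marginal <- a$cloverleafs[[tr]]$n_match <
            0.9 * a$cloverleafs[[tr]]$n_pairable
          dev_pos <- marginal && !is.null(med[[tr]]) &&
            abs(st - med[[tr]][["start"]]) > 2
          if (dev_pos) {
            ## re-fold pinned to the orthologous consensus interval; the
            ## positional evidence justifies a relaxed score threshold
            win <- c(max(0, med[[tr]][["start"]] - 2),
                     med[[tr]][["start"]] + med[[tr]][["len"]] + 2)
            fc <- find_cloverleaf(seq_p, tr, TRNA_ANTICODONS[[tr]],
                                  strand_tr, window = win,
                                  geometry = modal[[tr]], min_frac = 0.65)
            if (!is.null(fc)) {
              geoms[[tr]] <- modal[[tr]]; wins[[tr]] <- win
              fracs[[tr]] <- 0.65
            }
          } else if (dev_geom) {
            ## re-fold with the orthologous geometry near the original
            win <- c(max(0, st - 15), st + med[[tr]][["len"]] + 15)
            fc <- find_cloverleaf(seq_p, tr, TRNA_ANTICODONS[[tr]],
                                  strand_tr, window = win,
                                  geometry = modal[[tr]])
            if (!is.null(fc)) {
              geoms[[tr]] <- modal[[tr]]; wins[[tr]] <- win
            }
          }
        } else if (tr %in% names(found_count) &&
                   found_count[[tr]] > n_taxa / 2 &&
                   !is.null(med[[tr]])) {
          ## found in most taxa but not here: relaxed threshold near the
          ## orthologous position
          win <- c(max(0, med[[tr]][["start"]] - 80),
                   med[[tr]][["start"]] + med[[tr]][["len"]] + 80)
          fc <- find_cloverleaf(seq_p, tr, TRNA_ANTICODONS[[tr]],
                                strand_tr, window = win,
                                geometry = modal[[tr]], min_frac = 0.65)
          if (!is.null(fc)) {
            geoms[[tr]] <- modal[[tr]]; wins[[tr]] <- win
            fracs[[tr]] <- 0.65
          }
        }
      }
      if (!length(geoms)) next
      redo <- tryCatch(
        suppressWarnings(annotate_segment(
          seq_p, parts[2], taxon = parts[1], trna_geometry = geoms,
          trna_window = wins, trna_min_frac = fracs, ...)),
        error = function(e) NULL)
      if (!is.null(redo) &&
          all(names(geoms) %in% names(redo$cloverleafs)))
        per_seg[[key]] <- redo
    }
  }
  features <- list(); spacers <- list(); cloverleafs <- list()
  for (key in names(per_seg)) {
    a <- per_seg[[key]]
    tx <- strsplit(key, "|", fixed = TRUE)[[1]][1]
    features[[length(features) + 1L]] <- a$features
    spacers[[length(spacers) + 1L]] <- a$spacers
    cloverleafs[[tx]] <- c(cloverleafs[[tx]] %||% list(), a$cloverleafs)
  }
  list(features = do.call(rbind, features),
       spacers = do.call(rbind, spacers),
       cloverleafs = cloverleafs)
}

#' Write annotations as GFF3
#'
#' @param features feature data frame (0-based half-open, as produced by
#'   [annotate_segment()]); converted to GFF3 1-based closed coordinates.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_gff3 <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  type_map <- c(PCG = "gene", tRNA = "tRNA", rRNA = "rRNA",
                control_region = "region", spacer = "region")
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    writeLines(sprintf("%s\tmitosig\t%s\t%d\t%d\t.\t%s\t.\tID=%s;taxon=%s",
      f$segment, type_map[[f$type]] %||% "region", f$start + 1L, f$end,
      f$strand, f$feature, f$taxon), con)
  }
  invisible(path)
}

#' Extract annotated gene sequences
#'
#' Returns gene-orientation sequences (minus-strand features are reverse
#' complemented).
#'
#' @param features feature data frame for one taxon/segment set.
#' @param segments taxon -> segment -> sequence nested list.
#' @return data frame with `taxon`, `feature`, `sequence`.
#' @export
extract_gene_sequences <- function(features, segments) {
  seqs <- character(nrow(features))
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    s <- substr(segments[[f$taxon]][[f$segment]], f$start + 1L, f$end)
    seqs[i] <- if (f$strand == "-") revcomp(s) else s
  }
  data.frame(taxon = features$taxon, feature = features$feature,
             sequence = seqs, stringsAsFactors = FALSE)
}
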