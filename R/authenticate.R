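# ---------------------------------------------------------------------------
# authenticate: terminal substitution profiles and the ancient-like verdict.
# ---------------------------------------------------------------------------

#' Terminal substitution profile of an alignment set
#'
#' Tallies all 12 reference->read substitution classes at each of the first
#' `K` positions from the 5' and from the 3' end of every aligned read,
#' together with the opportunity counts (reference bases of the relevant
#' class at that offset). Reverse-strand alignments are reoriented so
#' offsets are read-relative: post-mortem deamination then shows up as
#' elevated C->T at 5' offsets and (for double-stranded libraries) G->A at
#' 3' offsets, decaying into the read.
#'
#' @param aln an `alignments` data.frame (end-to-end on `reference`).
#' @param reference the reference DNA string the alignments refer to.
#' @param K number of terminal positions profiled per end (default 25).
#' @return a `damage_profile`: list with `counts` (2 x K x 4 x 4 array,
#'   ends x offset x ref-base x read-base), `opportunities` (2 x K x 4),
#'   `frequencies`, headline series `ct5` and `ga3`, `K`, `n_reads`.
#' @export
damage_profile <- function(aln, reference, K = 25) {
  L <- nchar(reference)
  if (nrow(aln) > 0 && any(aln$start + aln$aligned_length > L))
    stop("alignment exceeds the reference length", call. = FALSE)
  ends <- c("5p", "3p")
  counts <- array(0L, dim = c(2, K, 4, 4),
                  dimnames = list(ends, NULL, .BASES, .BASES))
  opp <- array(0L, dim = c(2, K, 4), dimnames = list(ends, NULL, .BASES))
  for (r in seq_len(nrow(aln))) {
    l <- aln$aligned_length[r]
    refslice <- substr(reference, aln$start[r] + 1L, aln$start[r] + l)
    readfwd <- aln$seq[r]
    if (aln$strand[r] == "-") {       # reorient to sequencing direction
      refslice <- revcomp(refslice)
      readfwd <- revcomp(readfwd)
    }
    rc <- strsplit(refslice, "", fixed = TRUE)[[1]]
    qc <- strsplit(readfwd, "", fixed = TRUE)[[1]]
    if (length(qc) != l) stop("read/reference length inconsistency", call. = FALSE)
    k <- min(K, l)
    f5 <- match(rc[seq_len(k)], .BASES)
    t5 <- match(qc[seq_len(k)], .BASES)
    f3 <- match(rc[l - seq_len(k) + 1L], .BASES)
    t3 <- match(qc[l - seq_len(k) + 1L], .BASES)
    ok5 <- !is.na(f5)
    opp[cbind(1L, which(ok5), f5[ok5])] <- opp[cbind(1L, which(ok5), f5[ok5])] + 1L
    sub5 <- ok5 & !is.na(t5)
    if (any(sub5)) {
      ix <- cbind(1L, which(sub5), f5[sub5], t5[sub5])
      counts[ix] <- counts[ix] + 1L
    }
    ok3 <- !is.na(f3)
    opp[cbind(2L, which(ok3), f3[ok3])] <- opp[cbind(2L, which(ok3), f3[ok3])] + 1L
    sub3 <- ok3 & !is.na(t3)
    if (any(sub3)) {
      ix <- cbind(2L, which(sub3), f3[sub3], t3[sub3])
      counts[ix] <- counts[ix] + 1L
    }
  }
  freq <- array(0, dim = dim(counts), dimnames = dimnames(counts))
  for (e in 1:2) for (b in 1:4) {
    o <- opp[e, , b]
    for (to in 1:4) freq[e, , b, to] <- ifelse(o > 0, counts[e, , b, to] / o, 0)
  }
  structure(list(counts = counts, opportunities = opp, frequencies = freq,
                 ct5 = freq[1, , "C", "T"], ga3 = freq[2, , "G", "A"],
                 K = K, n_reads = nrow(aln)),
            class = "damage_profile")
}

#' @export
print.damage_profile <- function(x, ...) {
  cat(sprintf("damage_profile: %d reads, K=%d; 5' C->T offset0 = %.3f, 3' G->A offset0 = %.3f\n",
              x$n_reads, x$K, x$ct5[1], x$ga3[1]))
  invisible(x)
}

#' Flatten a damage profile to a long table
#'
#' One row per end x offset x substitution class, suitable for TSV export.
#'
#' @param x a `damage_profile`.
#' @param ... unused.
#' @return data.frame with `end`, `offset` (0-based), `from`, `to`, `count`,
#'   `opportunities`, `frequency`.
#' @export
as.data.frame.damage_profile <- function(x, ...) {
  grid <- expand.grid(end = c("5p", "3p"), offset = seq_len(x$K) - 1L,
                      from = .BASES, to = .BASES, stringsAsFactors = FALSE)
  grid <- grid[grid$from != grid$to, ]
  grid$count <- mapply(function(e, o, f, t)
    x$counts[e, o + 1L, f, t], grid$end, grid$offset, grid$from, grid$to)
  grid$opportunities <- mapply(function(e, o, f)
    x$opportunities[e, o + 1L, f], grid$end, grid$offset, grid$from)
  grid$frequency <- ifelse(grid$opportunities > 0,
                           grid$count / grid$opportunities, 0)
  rownames(grid) <- NULL
  grid
}

#' Ancient-likeness verdict from a damage profile
#'
#' The decision rule is conservative and explicit: a read set is flagged
#' ancient-like when the terminal (offset 0) 5' C->T rate reaches
#' `terminal_threshold` (default 0.10, below the >0.13 range typical of
#' authentic ancient samples) AND a two-proportion z-test of terminal versus
#' interior C->T rates exceeds 3.
#'
#' @param profile a `damage_profile`.
#' @param terminal_threshold minimum offset-0 C->T frequency.
#' @param interior_window inclusive 0-based offset range for the interior
#'   rate (default 10..20).
#' @return list with `ancient_like`, `terminal_rate`, `interior_rate`,
#'   `two_proportion_z`, `status` (`"ok"` or `"undefined"` when the interior
#'   has no C opportunities).
#' @export
damage_verdict <- function(profile, terminal_threshold = 0.10,
                           interior_window = c(10, 20)) {
  term_opp <- profile$opportunities[1, 1, "C"]
  if (term_opp == 0)
    stop("no offset-0 C opportunities; profile too sparse for a verdict",
         call. = FALSE)
  term_ct <- profile$counts[1, 1, "C", "T"]
  idx <- (interior_window[1]:interior_window[2]) + 1L
  idx <- idx[idx <= profile$K]
  int_opp <- sum(profile$opportunities[1, idx, "C"])
  int_ct <- sum(profile$counts[1, idx, "C", "T"])
  if (int_opp == 0) {
    return(list(ancient_like = NA, terminal_rate = term_ct / term_opp,
                interior_rate = NA_real_, two_proportion_z = NA_real_,
                status = "undefined"))
  }
  p1 <- term_ct / term_opp
  p2 <- int_ct / int_opp
  pp <- (term_ct + int_ct) / (term_opp + int_opp)
  z <- if (pp %in% c(0, 1)) 0 else
    (p1 - p2) / sqrt(pp * (1 - pp) * (1 / term_opp + 1 / int_opp))
  list(ancient_like = (p1 >= terminal_threshold) && (z > 3),
       terminal_rate = p1, interior_rate = p2, two_proportion_z = z,
       status = "ok")
}
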