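# ---------------------------------------------------------------------------
# readmap: desk-scale end-to-end mapper, SAM text I/O, alignment filters and
# the competitive multi-reference partition.
# ---------------------------------------------------------------------------

.as_read_table <- function(reads) {
  if (is.data.frame(reads)) {
    stopifnot(all(c("id", "seq") %in% names(reads)))
    return(reads[, c("id", "seq")])
  }
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    return(read_fastq(reads))
  if (is.character(reads)) {
    if (is.null(names(reads))) stop("character reads must be named by read id", call. = FALSE)
    return(data.frame(id = names(reads), seq = unname(reads), stringsAsFactors = FALSE))
  }
  stop("unsupported read input", call. = FALSE)
}

#' Map reads end-to-end against a single reference
#'
#' Exhaustively scores every end-to-end substitution-only placement of each
#' read on both strands of the reference and reports the best one when its
#' mismatch score is within `ceiling(max_mismatch_rate * length)`. Ties
#' across placements yield `map_score` 0 (non-unique) and retain one
#' placement by the deterministic rule lowest start, then forward strand;
#' unique placements get `map_score` 37. With `damage_tolerant = TRUE`,
#' mismatches of the deamination classes (reference C read T, reference G
#' read A, as seen on the forward-oriented aligned sequence; the two classes
#' cover C->T on either strand of a double-stranded library) count half.
#'
#' This mapper is mismatch-only (no gaps) by design: the pipeline's
#' production-scale inputs arrive as SAM from external mappers, and the
#' gap-free desk-scale version is verifiable against a brute-force oracle.
#' Non-ACGT bases in read or reference mismatch everywhere.
#'
#' @param reads `ancient_reads` data.frame, named character vector, or FASTQ
#'   path.
#' @param reference single (optionally named) DNA string.
#' @param max_mismatch_rate maximum mismatch score as a fraction of read
#'   length.
#' @param min_len reads shorter than this are skipped (counted, not mapped).
#' @param damage_tolerant half-weight deamination-class mismatches.
#' @return an `alignments` data.frame (`read_id`, `ref_id`, `start` 0-based,
#'   `strand`, `aligned_length`, `edit_distance`, `score`, `map_score`,
#'   `seq` = forward-oriented aligned sequence) with attributes
#'   `unmapped_ids`, `skipped_short_ids`, `ref_id`, `ref_length`.
#' @export
map_reads_end_to_end <- function(reads, reference, max_mismatch_rate = 0.1,
                                 min_len = 35, damage_tolerant = FALSE) {
  rd <- .as_read_table(reads)
  ref_id <- if (!is.null(names(reference))) names(reference)[1] else "ref"
  refseq <- toupper(unname(reference[1]))
  L <- nchar(refseq)
  if (is.na(L) || L == 0) stop("empty reference", call. = FALSE)
  refe <- .encode_seq(refseq)
  refe[is.na(refe)] <- 0L
  # weight lookup W[read_code * 5 + ref_code + 1]; codes 0 (non-ACGT) .. 4
  W <- matrix(1, 5, 5)                     # rows ref+1, cols read+1
  for (i in 2:5) W[i, i] <- 0
  W[1, 1] <- 1                             # non-ACGT never matches
  if (damage_tolerant) {
    W[3, 5] <- 0.5                         # ref C, read T
    W[4, 2] <- 0.5                         # ref G, read A
  }
  Wv <- as.vector(W)                       # Wv[(read)*5 + ref + 1]

  n <- nrow(rd)
  res <- vector("list", n)
  unmapped <- character(0)
  skipped <- character(0)
  for (r in seq_len(n)) {
    sq <- toupper(rd$seq[r])
    l <- nchar(sq)
    if (l < min_len) { skipped <- c(skipped, rd$id[r]); next }
    if (l > L) { unmapped <- c(unmapped, rd$id[r]); next }
    budget <- ceiling(max_mismatch_rate * l)
    np <- L - l + 1L
    cand <- list()
    for (st in c("+", "-")) {
      oriented <- if (st == "+") sq else revcomp(sq)
      q <- .encode_seq(oriented)
      q[is.na(q)] <- 0L
      s <- numeric(np)
      for (i in seq_len(l)) {
        s <- s + Wv[refe[i:(i + np - 1L)] + q[i] * 5L + 1L]
      }
      cand[[st]] <- list(scores = s, q = q, oriented = oriented)
    }
    m <- min(cand[["+"]]$scores, cand[["-"]]$scores)
    if (m > budget) { unmapped <- c(unmapped, rd$id[r]); next }
    hits_p <- which(cand[["+"]]$scores == m)
    hits_m <- which(cand[["-"]]$scores == m)
    n_hits <- length(hits_p) + length(hits_m)
    # deterministic retention: lowest start, '+' preferred at equal start
    best_start <- min(c(hits_p, hits_m))
    best_strand <- if (best_start %in% hits_p) "+" else "-"
    ch <- cand[[best_strand]]
    slice <- refe[best_start:(best_start + l - 1L)]
    edit <- sum(slice != ch$q | slice == 0L)
    res[[r]] <- data.frame(read_id = rd$id[r], ref_id = ref_id,
                           start = best_start - 1L, strand = best_strand,
                           aligned_length = l, edit_distance = as.integer(edit),
                           score = m, map_score = if (n_hits > 1L) 0L else 37L,
                           seq = ch$oriented, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(read_id = character(0), ref_id = character(0),
                      start = integer(0), strand = character(0),
                      aligned_length = integer(0), edit_distance = integer(0),
                      score = numeric(0), map_score = integer(0),
                      seq = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("alignments", "data.frame"),
            unmapped_ids = unmapped, skipped_short_ids = skipped,
            ref_id = ref_id, ref_length = L)
}

#' Write alignments as SAM v1 text
#'
#' Emits a minimal header (`@HD`, `@SQ`) and one record per alignment with
#' flag 0/16, 1-based POS, MAPQ = `map_score`, an all-match CIGAR and the
#' `NM:i:` edit-distance tag; SEQ is the forward-oriented aligned sequence
#' (SAM convention).
#'
#' @param aln an `alignments` data.frame.
#' @param path output file.
#' @param ref_id,ref_length reference metadata (default from `aln`
#'   attributes).
#' @return invisibly, `path`.
#' @export
write_sam <- function(aln, path, ref_id = attr(aln, "ref_id"),
                      ref_length = attr(aln, "ref_length")) {
  if (is.null(ref_id) || is.null(ref_length))
    stop("reference metadata required (ref_id, ref_length)", call. = FALSE)
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", ref_id, as.integer(ref_length)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                  aln$read_id, ifelse(aln$strand == "-", 16L, 0L), aln$ref_id,
                  aln$start + 1L, aln$map_score, aln$aligned_length,
                  aln$seq, aln$edit_distance)
  writeLines(c(header, body), path)
  invisible(path)
}

.md_mismatches <- function(md) {
  # count reference letters in an MD:Z string, excluding deletion runs (^...)
  md <- gsub("\\^[A-Z]+", "", md)
  sum(gregexpr("[A-Z]", md)[[1]] > 0)
}

#' Read a SAM text file into alignment records
#'
#' Requires `NM` tags for edit distance; when `NM` is absent it is recovered
#' from the `MD` tag, and records carrying neither are an error. The 1-based
#' SAM `POS` is converted to the package's 0-based `start`. Malformed headers
#' or records raise errors naming the offending line.
#'
#' @param path SAM file.
#' @return an `alignments` data.frame (see [map_reads_end_to_end()]); the
#'   internal weighted `score` column is not representable in SAM and is NA.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  recs <- list()
  ref_id <- NULL
  ref_length <- NULL
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "@")) {
      if (startsWith(ln, "@SQ")) {
        f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
        sn <- sub("^SN:", "", grep("^SN:", f, value = TRUE)[1])
        lnv <- sub("^LN:", "", grep("^LN:", f, value = TRUE)[1])
        if (is.na(sn) || is.na(lnv))
          stop(sprintf("malformed @SQ header at line %d", i), call. = FALSE)
        ref_id <- sn; ref_length <- as.integer(lnv)
      }
      next
    }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 11)
      stop(sprintf("malformed SAM record at line %d: %d fields", i, length(f)),
           call. = FALSE)
    flag <- suppressWarnings(as.integer(f[2]))
    pos <- suppressWarnings(as.integer(f[4]))
    if (is.na(flag) || is.na(pos))
      stop(sprintf("malformed SAM record at line %d", i), call. = FALSE)
    cig <- f[6]
    mlen <- sum(as.integer(regmatches(cig, gregexpr("[0-9]+(?=[M=X])", cig, perl = TRUE))[[1]]))
    tags <- if (length(f) > 11) f[12:length(f)] else character(0)
    nm_tag <- grep("^NM:i:", tags, value = TRUE)
    md_tag <- grep("^MD:Z:", tags, value = TRUE)
    if (length(nm_tag)) {
      nm <- as.integer(sub("^NM:i:", "", nm_tag[1]))
    } else if (length(md_tag)) {
      nm <- .md_mismatches(sub("^MD:Z:", "", md_tag[1]))
    } else {
      stop(sprintf("record at line %d lacks both NM and MD tags", i), call. = FALSE)
    }
    recs[[length(recs) + 1L]] <- data.frame(
      read_id = f[1], ref_id = f[3], start = pos - 1L,
      strand = if (bitwAnd(flag, 16L) > 0L) "-" else "+",
      aligned_length = if (mlen > 0) mlen else nchar(f[10]),
      edit_distance = nm, score = NA_real_,
      map_score = as.integer(f[5]), seq = f[10], stringsAsFactors = FALSE)
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(read_id = character(0), ref_id = character(0), start = integer(0),
               strand = character(0), aligned_length = integer(0),
               edit_distance = integer(0), score = numeric(0),
               map_score = integer(0), seq = character(0), stringsAsFactors = FALSE)
  structure(out, class = c("alignments", "data.frame"),
            ref_id = ref_id, ref_length = ref_length,
            unmapped_ids = character(0), skipped_short_ids = character(0))
}

#' Filter alignments on mapping quality and aligned length
#'
#' The pipeline's pass/fail gate: records are kept when
#' `map_score >= min_map_score` and `aligned_length >= min_len`. The
#' mitochondrial mode of the upstream processing uses `min_len = 25`.
#'
#' @param aln an `alignments` data.frame.
#' @param min_map_score minimum mapping quality (default 25).
#' @param min_len minimum aligned length in bp (default 35).
#' @return filtered `alignments`; `attr(,"removed")` counts removals by
#'   reason (`low_score`, `short`, with doubly-failing reads counted under
#'   both).
#' @export
filter_alignments <- function(aln, min_map_score = 25, min_len = 35) {
  low <- aln$map_score < min_map_score
  short <- aln$aligned_length < min_len
  out <- aln[!(low | short), , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("unmapped_ids", "skipped_short_ids", "ref_id", "ref_length"))
    attr(out, a) <- attr(aln, a)
  attr(out, "removed") <- c(low_score = sum(low), short = sum(short))
  class(out) <- c("alignments", "data.frame")
  out
}

.check_unique_records <- function(aln, label) {
  d <- duplicated(aln$read_id)
  if (!any(d)) return(aln)
  # identical duplicate rows are tolerated (deduplicated); conflicting ones are not
  key <- paste(aln$read_id, aln$start, aln$strand, aln$edit_distance)
  if (anyDuplicated(aln$read_id[!duplicated(key)]))
    stop(sprintf("conflicting duplicate read ids in alignment set %s", label),
         call. = FALSE)
  aln[!duplicated(aln$read_id), , drop = FALSE]
}

#' Competitive partition of reads across references
#'
#' Classifies each read of the universe by which filtered alignment sets
#' accept it. In `presence` mode a read mapped to exactly one reference is
#' unique to it and a read mapped to two or more is shared. In
#' `edit_arbitration` mode a multiply-mapped read is assigned to the
#' reference with strictly smallest edit distance (assignment by least edit
#' difference); ties remain shared. The three classes plus the unmapped
#' tally are exhaustive and pairwise disjoint.
#'
#' @param aln_a,aln_b filtered `alignments` against references A and B.
#' @param mode `"presence"` or `"edit_arbitration"`.
#' @param read_ids the read universe; defaults to all ids seen in the two
#'   alignment sets plus their recorded unmapped/skipped ids.
#' @return a `partition_result`: list with `unique_a`, `unique_b`, `shared`
#'   (character id sets), `n_unmapped`, `mode`, `n_input`.
#' @export
competitive_partition <- function(aln_a, aln_b,
                                  mode = c("presence", "edit_arbitration"),
                                  read_ids = NULL) {
  mode <- match.arg(mode)
  res <- competitive_partition_k(list(a = aln_a, b = aln_b), mode = mode,
                                 read_ids = read_ids)
  structure(list(unique_a = res$unique$a, unique_b = res$unique$b,
                 shared = res$shared, n_unmapped = res$n_unmapped,
                 mode = mode, n_input = res$n_input),
            class = "partition_result")
}

#' Competitive partition across k references
#'
#' Generalisation of [competitive_partition()] used for RefSeq-style
#' screening: a read mapped to two or more references lands in one shared
#' pool (no pairwise sub-pools) unless edit arbitration singles out a
#' strictly best reference.
#'
#' @param aln_list named list of filtered `alignments`.
#' @param mode `"presence"` or `"edit_arbitration"`.
#' @param read_ids the read universe (see [competitive_partition()]).
#' @return list with `unique` (named list of id sets), `shared`,
#'   `n_unmapped`, `mode`, `n_input`.
#' @export
competitive_partition_k <- function(aln_list,
                                    mode = c("presence", "edit_arbitration"),
                                    read_ids = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(aln_list) >= 2, !is.null(names(aln_list)))
  aln_list <- Map(.check_unique_records, aln_list, names(aln_list))
  if (is.null(read_ids)) {
    read_ids <- unique(unlist(c(lapply(aln_list, function(a) a$read_id),
                                lapply(aln_list, attr, "unmapped_ids"),
                                lapply(aln_list, attr, "skipped_short_ids"))))
  }
  hit <- vapply(aln_list, function(a) read_ids %in% a$read_id,
                logical(length(read_ids)))
  if (is.null(dim(hit))) hit <- matrix(hit, nrow = length(read_ids))
  nhits <- rowSums(hit)
  uniq <- lapply(seq_along(aln_list), function(j)
    read_ids[hit[, j] & nhits == 1L])
  names(uniq) <- names(aln_list)
  shared <- read_ids[nhits >= 2L]
  if (mode == "edit_arbitration" && length(shared)) {
    ed <- vapply(aln_list, function(a)
      as.numeric(a$edit_distance[match(shared, a$read_id)]),
      numeric(length(shared)))
    if (is.null(dim(ed))) ed <- matrix(ed, nrow = length(shared))
    still_shared <- logical(length(shared))
    for (i in seq_along(shared)) {
      e <- ed[i, ]
      winners <- which(e == min(e, na.rm = TRUE) & !is.na(e))
      if (length(winners) == 1L) {
        uniq[[winners]] <- c(uniq[[winners]], shared[i])
      } else {
        still_shared[i] <- TRUE
      }
    }
    shared <- shared[still_shared]
  }
  n_unmapped <- length(read_ids) - length(shared) - sum(lengths(uniq))
  out <- list(unique = uniq, shared = shared, n_unmapped = n_unmapped,
              mode = mode, n_input = length(read_ids))
  stopifnot(sum(lengths(uniq)) + length(shared) + n_unmapped == length(read_ids))
  out
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("partition (%s): unique_a=%d unique_b=%d shared=%d unmapped=%d of %d\n",
              x$mode, length(x$unique_a), length(x$unique_b), length(x$shared),
              x$n_unmapped, x$n_input))
  invisible(x)
}

#' Extract an order-preserving subset of reads
#'
#' @param reads `ancient_reads` data.frame, named character vector, or FASTQ
#'   path.
#' @param ids read ids to keep; unknown ids raise an error listing them.
#' @return data.frame subset in the original read order.
#' @export
extract_read_subset <- function(reads, ids) {
  rd <- if (is.data.frame(reads)) reads else .as_read_table(reads)
  missing <- setdiff(ids, rd$id)
  if (length(missing))
    stop("unknown read ids: ", paste(missing, collapse = ", "), call. = FALSE)
  out <- rd[rd$id %in% ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-position read bases from alignments
#'
#' Collects, for each requested 1-based reference position, the
#' forward-oriented base of every alignment covering it. Used by the
#' pseudo-haploid caller and the branch-support tally.
#'
#' @param aln an `alignments` data.frame.
#' @param positions integer vector of 1-based reference positions.
#' @return named list (by position) of character vectors of bases.
#' @export
pileup_bases <- function(aln, positions) {
  out <- vector("list", length(positions))
  names(out) <- as.character(positions)
  if (nrow(aln) == 0) {
    for (i in seq_along(out)) out[[i]] <- character(0)
    return(out)
  }
  starts <- aln$start          # 0-based
  ends <- aln$start + aln$aligned_length
  for (i in seq_along(positions)) {
    p <- positions[i]          # 1-based; covers iff start < p <= end
    cov <- which(starts < p & p <= ends)
    out[[i]] <- if (length(cov))
      substring(aln$seq[cov], p - starts[cov], p - starts[cov]) else character(0)
  }
  out
}

#' Base-count pileup matrix over a whole reference
#'
#' @param aln an `alignments` data.frame.
#' @param ref_length reference length.
#' @return integer matrix `ref_length` x 4 (columns A,C,G,T) of base counts.
#' @export
pileup_counts <- function(aln, ref_length) {
  m <- matrix(0L, nrow = ref_length, ncol = 4,
              dimnames = list(NULL, .BASES))
  for (r in seq_len(nrow(aln))) {
    if (aln$start[r] + aln$aligned_length[r] > ref_length)
      stop("alignment exceeds the reference length", call. = FALSE)
    codes <- .encode_seq(aln$seq[r])
    ok <- !is.na(codes)
    rows <- aln$start[r] + which(ok)
    idx <- cbind(rows, codes[ok])
    m[idx] <- m[idx] + 1L
  }
  m
}
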