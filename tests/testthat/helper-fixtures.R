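# Shared fixtures and independent oracles. Everything here is deliberately
# naive (loops, substring scans) so it stays independent of the package's
# vectorised implementations.

# brute-force end-to-end mapper: substring comparison at every position on
# both strands, unit mismatch weights
bf_map_one <- function(read, refseq, max_mismatch_rate) {
  l <- nchar(read)
  L <- nchar(refseq)
  budget <- ceiling(max_mismatch_rate * l)
  best <- NULL
  hits <- 0L
  for (strand in c("+", "-")) {
    q <- if (strand == "+") read else revcomp(read)
    qc <- strsplit(q, "")[[1]]
    for (s in 1:(L - l + 1)) {
      rc <- strsplit(substr(refseq, s, s + l - 1), "")[[1]]
      mm <- sum(rc != qc | !(rc %in% c("A", "C", "G", "T")) |
                  !(qc %in% c("A", "C", "G", "T")))
      if (is.null(best) || mm < best$mm) {
        best <- list(mm = mm, start = s - 1L, strand = strand)
        hits <- 1L
      } else if (mm == best$mm) {
        hits <- hits + 1L
        # deterministic retention: lowest start, then "+"
        if (s - 1L < best$start) best <- list(mm = mm, start = s - 1L, strand = strand)
      }
    }
  }
  if (best$mm > budget) return(NULL)
  list(start = best$start, strand = best$strand, edit = best$mm,
       unique = hits == 1L)
}

# naive rescaled Hamming distance, double loop over sites
naive_hamming <- function(G, rescale = TRUE) {
  n <- nrow(G)
  S <- ncol(G)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    raw <- 0
    m <- 0
    for (s in seq_len(S)) {
      if (!is.na(G[i, s]) && !is.na(G[j, s])) {
        raw <- raw + abs(G[i, s] - G[j, s])
        m <- m + 1
      }
    }
    D[i, j] <- if (i == j) 0 else if (rescale) raw * S / m else raw
  }
  D
}

# alignments records taken straight from simulation truth (no mapping):
# forward-oriented sequence per SAM convention
truth_alignments <- function(reads, ref_id = "ref") {
  data.frame(read_id = reads$id, ref_id = ref_id, start = reads$start,
             strand = reads$strand, aligned_length = reads$end - reads$start,
             edit_distance = 0L, score = 0, map_score = 37L,
             seq = ifelse(reads$strand == "-", revcomp(reads$seq), reads$seq),
             stringsAsFactors = FALSE)
}

# closed-form three-lineage expectation of the derived-allele fraction:
# expected branch lengths conditional on topology, mutation uniform on the
# branches separating the first two lineages
three_lineage_fraction <- function() {
  # E[T3] = 1/3 (three lineages), E[T2] = 1 (two lineages)
  ET3 <- 1 / 3
  ET2 <- 1
  # carrier set {a}: a's external branch; length T3 in topologies ((a,b),c)
  # and ((a,c),b), T3+T2 in ((b,c),a); topologies equiprobable
  len_a <- (ET3 + ET3 + (ET3 + ET2)) / 3
  len_b <- len_a
  # carrier {a,c}: internal branch of ((a,c),b) only, length T2
  len_ac <- ET2 / 3
  len_bc <- ET2 / 3
  (len_ac + len_bc) / (len_a + len_b + len_ac + len_bc)
}

# toy six-leaf rooted tree with outgroup O used by the placement tests
toy_tree <- function() {
  ape::read.tree(text = "(((A:1,B:1):1,(C:1,D:1):1):1,(E:1,O:1):1);")
}
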