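# ---------------------------------------------------------------------------
# simdata: every synthetic input the pipeline needs, with provenance truth.
# ---------------------------------------------------------------------------

#' Post-mortem deamination damage model
#'
#' Describes the terminal cytosine-deamination signal of ancient DNA: C->T
#' substitutions at the 5' end and (for double-stranded library preparations)
#' G->A at the 3' end, with a per-position exponential decay so that the rate
#' at read offset i is `delta * exp(-decay * i)`. Single-stranded libraries
#' show C->T decay from both ends and no G->A.
#'
#' Defaults (terminal rate 0.30, decay 0.30 per position, double-stranded)
#' describe a well-preserved permafrost/cave-sediment sample; observed
#' terminal rates above roughly 0.13 are typical of authentic ancient
#' material.
#'
#' @param delta5 probability of C->T at 5'-terminal offset 0.
#' @param delta3 probability of G->A at 3'-terminal offset 0
#'   (reinterpreted as the 3' C->T rate in single-stranded mode).
#' @param decay exponential decay constant per position (>= 0).
#' @param library_mode `"double_stranded"` or `"single_stranded"`.
#' @return an object of class `damage_model`.
#' @export
damage_model <- function(delta5 = 0.3, delta3 = 0.3, decay = 0.3,
                         library_mode = c("double_stranded", "single_stranded")) {
  .check_prob(delta5, "delta5")
  .check_prob(delta3, "delta3")
  if (decay < 0) stop("`decay` must be >= 0", call. = FALSE)
  library_mode <- match.arg(library_mode)
  structure(list(delta5 = delta5, delta3 = delta3, decay = decay,
                 library_mode = library_mode),
            class = "damage_model")
}

#' Fragment length model for ancient DNA
#'
#' Sediment aDNA is dominated by short fragments. The default family is a
#' shifted geometric: `min_len + Geometric(p)` with `p` chosen so the mean is
#' `mean_len`; a lognormal alternative (`dispersion` = sdlog) is provided and
#' truncated at `min_len`. The minimum retained length in the pipeline's
#' upstream processing is 25 bp, so `min_len` may not go below that.
#'
#' @param min_len minimum fragment length in bp (>= 25).
#' @param mean_len mean fragment length in bp (> min_len).
#' @param dispersion lognormal sdlog shape parameter (ignored for the
#'   geometric family).
#' @param family `"shifted_geometric"` or `"lognormal"`.
#' @return an object of class `fragment_model`.
#' @export
fragment_model <- function(min_len = 35, mean_len = 55, dispersion = 0.35,
                           family = c("shifted_geometric", "lognormal")) {
  family <- match.arg(family)
  if (min_len < 25) stop("`min_len` must be >= 25 bp", call. = FALSE)
  if (mean_len <= min_len) stop("`mean_len` must exceed `min_len`", call. = FALSE)
  if (dispersion <= 0) stop("`dispersion` must be > 0", call. = FALSE)
  structure(list(min_len = as.integer(min_len), mean_len = mean_len,
                 dispersion = dispersion, family = family),
            class = "fragment_model")
}

.draw_fragment_lengths <- function(n, fm) {
  if (fm$family == "shifted_geometric") {
    p <- 1 / (fm$mean_len - fm$min_len + 1)
    fm$min_len + rgeom(n, p)
  } else {
    sdlog <- fm$dispersion
    meanlog <- log(fm$mean_len) - sdlog^2 / 2
    len <- round(rlnorm(n, meanlog, sdlog))
    pmax(len, fm$min_len)
  }
}

#' Simulate a pair of diverged reference species
#'
#' Generates an ancestral sequence and two descendant references that differ
#' only by substitutions: each site independently differs between the two
#' references with probability `divergence`, the substituted base drawn
#' uniformly among the three alternatives and applied to one of the two
#' descendants at random. Stands in for a pair of closely related reference
#' genomes used in competitive mapping.
#'
#' @param length sequence length in bp.
#' @param divergence per-site difference probability in \[0, 0.75).
#' @param seed integer seed; the result is bit-identical under the same seed.
#' @return a `species_pair` with fields `ancestor`, `ref_a`, `ref_b` and
#'   0-based `diff_positions`.
#' @export
simulate_species_pair <- function(length, divergence, seed) {
  if (length < 1) stop("`length` must be >= 1", call. = FALSE)
  if (!is.numeric(divergence) || divergence < 0 || divergence >= 0.75)
    stop("`divergence` must lie in [0, 0.75)", call. = FALSE)
  .check_seed(seed)
  withr::with_seed(seed, {
    anc <- sample(.BASES, length, replace = TRUE)
    diff <- which(runif(length) < divergence)
    a <- anc
    b <- anc
    if (length(diff)) {
      mutate_a <- runif(length(diff)) < 0.5
      newbase <- vapply(anc[diff], function(x) sample(setdiff(.BASES, x), 1),
                        character(1), USE.NAMES = FALSE)
      a[diff[mutate_a]] <- newbase[mutate_a]
      b[diff[!mutate_a]] <- newbase[!mutate_a]
    }
    structure(list(ancestor = paste(anc, collapse = ""),
                   ref_a = paste(a, collapse = ""),
                   ref_b = paste(b, collapse = ""),
                   diff_positions = diff - 1L),
              class = "species_pair")
  })
}

#' @export
print.species_pair <- function(x, ...) {
  cat(sprintf("species_pair: %d bp, %d differing sites (%.4f per site)\n",
              nchar(x$ref_a), length(x$diff_positions),
              length(x$diff_positions) / nchar(x$ref_a)))
  invisible(x)
}

# --- coalescent machinery ---------------------------------------------------

# Structured coalescent: exponential waiting times, random pair merges within
# demes, cross-deme coalescence forbidden until the demes merge per the
# schedule. Returns the branch list (leaf set + length) of the genealogy.
.coalescent_branches <- function(group_sizes, schedule = NULL) {
  n <- sum(group_sizes)
  grp <- rep(seq_along(group_sizes), group_sizes)
  leaves <- as.list(seq_len(n))
  start <- numeric(n)
  if (is.null(schedule)) schedule <- data.frame(time = numeric(0), from = integer(0), to = integer(0))
  schedule <- schedule[order(schedule$time), , drop = FALSE]
  ev <- 1L
  t <- 0
  br_leaves <- vector("list", 2L * (n - 1L))
  br_len <- numeric(2L * (n - 1L))
  nb <- 0L
  while (length(leaves) > 1L) {
    counts <- tabulate(grp, nbins = max(grp))
    rates <- counts * (counts - 1) / 2
    total <- sum(rates)
    wait <- if (total > 0) rexp(1, total) else Inf
    if (ev <= nrow(schedule) && t + wait > schedule$time[ev]) {
      t <- schedule$time[ev]
      grp[grp == schedule$from[ev]] <- schedule$to[ev]
      ev <- ev + 1L
      next
    }
    if (!is.finite(wait))
      stop("isolated lineages cannot coalesce; check the merge schedule", call. = FALSE)
    t <- t + wait
    g <- sample.int(length(rates), 1, prob = rates)
    members <- which(grp == g)
    pair <- members[sample.int(length(members), 2)]
    for (x in pair) {
      nb <- nb + 1L
      br_leaves[[nb]] <- leaves[[x]]
      br_len[nb] <- t - start[x]
    }
    merged <- sort(c(leaves[[pair[1]]], leaves[[pair[2]]]))
    keep <- setdiff(seq_along(leaves), pair)
    leaves <- c(leaves[keep], list(merged))
    start <- c(start[keep], t)
    grp <- c(grp[keep], g)
  }
  list(leaves = br_leaves[seq_len(nb)], lengths = br_len[seq_len(nb)], tmrca = t)
}

.mutate_branches <- function(branches, n_hap, theta, chrom_length) {
  counts <- rpois(length(branches$lengths), theta / 2 * branches$lengths)
  S <- sum(counts)
  if (S > chrom_length)
    stop("more segregating sites than chromosome positions; increase `chrom_length`",
         call. = FALSE)
  if (S == 0L) {
    return(list(haplotypes = matrix(0L, n_hap, 0), positions = integer(0)))
  }
  positions <- sort(sample.int(chrom_length, S))
  site_branch <- rep.int(seq_along(counts), counts)
  if (length(site_branch) > 1L) site_branch <- sample(site_branch)
  H <- matrix(0L, n_hap, S)
  for (s in seq_len(S)) H[branches$leaves[[site_branch[s]]], s] <- 1L
  list(haplotypes = H, positions = positions)
}

#' Simulate a coalescent genotype panel
#'
#' Standard neutral coalescent for one panmictic population or two
#' populations with a clean split at `split_time` (in coalescent units of 2N
#' generations; cross-population coalescence is forbidden more recently than
#' the split). Mutations follow the infinite-sites model at rate `theta/2`
#' per lineage per unit time, polarised so that 0 is the ancestral/reference
#' allele and 1 the derived/alternate allele; every column is genuinely
#' polymorphic. Haplotypes 2k-1 and 2k form diploid individual k.
#'
#' @param n_diploids_per_pop diploid sample size per population (>= 1).
#' @param n_pops 1 or 2.
#' @param split_time scaled split time (ignored when `n_pops = 1`); 0 gives a
#'   panmictic population.
#' @param theta scaled mutation rate (> 0); for a single diploid the expected
#'   number of heterozygous sites is `theta`.
#' @param seed integer seed.
#' @param chrom_length length of the virtual chromosome carrying the sites.
#' @return a `coalescent_panel` with `haplotypes` (H x S 0/1 matrix),
#'   1-based `positions`, `pop_labels` per individual, and the parameters.
#' @export
simulate_coalescent_panel <- function(n_diploids_per_pop, n_pops = 1,
                                      split_time = 0, theta, seed,
                                      chrom_length = 1e6) {
  if (!n_pops %in% c(1, 2)) stop("`n_pops` must be 1 or 2", call. = FALSE)
  if (n_diploids_per_pop < 1) stop("`n_diploids_per_pop` must be >= 1", call. = FALSE)
  if (theta <= 0) stop("`theta` must be > 0", call. = FALSE)
  if (split_time < 0) stop("`split_time` must be >= 0", call. = FALSE)
  .check_seed(seed)
  n_hap_per_pop <- 2L * as.integer(n_diploids_per_pop)
  withr::with_seed(seed, {
    if (n_pops == 1) {
      br <- .coalescent_branches(n_hap_per_pop)
    } else {
      br <- .coalescent_branches(rep(n_hap_per_pop, 2),
                                 data.frame(time = split_time, from = 2L, to = 1L))
    }
    mut <- .mutate_branches(br, n_hap_per_pop * n_pops, theta, chrom_length)
    structure(list(haplotypes = mut$haplotypes,
                   positions = mut$positions,
                   pop_labels = rep(paste0("pop", seq_len(n_pops)),
                                    each = n_diploids_per_pop),
                   split_time = if (n_pops == 2) split_time else 0,
                   theta = theta, chrom_length = chrom_length),
              class = "coalescent_panel")
  })
}

#' Simulate a genome-scale panel of unlinked loci
#'
#' Concatenates `n_loci` independent coalescent panels (one non-recombining
#' genealogy each) into a single genotype panel, emulating genome-wide
#' unlinked SNPs. A single-locus panel is one genealogy, so its sites are
#' perfectly linked; statistics whose standard errors assume independent
#' linkage blocks (the f4 block jackknife in particular) are only calibrated
#' on multi-locus panels. Loci are laid out on consecutive coordinate
#' windows of `chrom_length` so site order follows the genome.
#'
#' @inheritParams simulate_coalescent_panel
#' @param n_loci number of independent loci.
#' @param theta_per_locus scaled mutation rate of each locus.
#' @param generator optional function `seed -> coalescent_panel` replacing
#'   the default single-locus generator (e.g. a [simulate_three_pop_panel()]
#'   closure).
#' @return a `coalescent_panel` with an extra per-site `locus` index.
#' @export
simulate_multilocus_panel <- function(n_loci, n_diploids_per_pop, n_pops = 1,
                                      split_time = 0, theta_per_locus, seed,
                                      chrom_length = 1e6, generator = NULL) {
  stopifnot(n_loci >= 1)
  .check_seed(seed)
  seeds <- withr::with_seed(seed, sample.int(2^30, n_loci))
  if (is.null(generator))
    generator <- function(s)
      simulate_coalescent_panel(n_diploids_per_pop, n_pops, split_time,
                                theta_per_locus, seed = s,
                                chrom_length = chrom_length)
  panels <- lapply(seeds, generator)
  ns <- vapply(panels, function(p) ncol(p$haplotypes), integer(1))
  H <- do.call(cbind, lapply(panels, `[[`, "haplotypes"))
  cl <- panels[[1]]$chrom_length
  positions <- unlist(lapply(seq_len(n_loci), function(i)
    panels[[i]]$positions + (i - 1) * cl))
  structure(list(haplotypes = H, positions = positions,
                 pop_labels = panels[[1]]$pop_labels,
                 split_time = panels[[1]]$split_time,
                 theta = panels[[1]]$theta,
                 chrom_length = n_loci * cl,
                 locus = rep(seq_len(n_loci), ns)),
            class = "coalescent_panel")
}

#' Simulate a three-population panel with nested splits
#'
#' Extension of [simulate_coalescent_panel()] used by the sparse-projection
#' tests: populations 1 and 2 merge at `split_recent`, and their ancestor
#' merges with population 3 at `split_deep`.
#'
#' @inheritParams simulate_coalescent_panel
#' @param split_recent,split_deep scaled split times, `split_recent <= split_deep`.
#' @return a `coalescent_panel` with three population labels.
#' @export
simulate_three_pop_panel <- function(n_diploids_per_pop, split_recent, split_deep,
                                     theta, seed, chrom_length = 1e6) {
  if (split_recent > split_deep) stop("`split_recent` must be <= `split_deep`", call. = FALSE)
  .check_seed(seed)
  n_hap <- 2L * as.integer(n_diploids_per_pop)
  withr::with_seed(seed, {
    br <- .coalescent_branches(rep(n_hap, 3),
                               data.frame(time = c(split_recent, split_deep),
                                          from = c(2L, 3L), to = c(1L, 1L)))
    mut <- .mutate_branches(br, n_hap * 3L, theta, chrom_length)
    structure(list(haplotypes = mut$haplotypes,
                   positions = mut$positions,
                   pop_labels = rep(paste0("pop", 1:3), each = n_diploids_per_pop),
                   split_time = split_deep, theta = theta,
                   chrom_length = chrom_length),
              class = "coalescent_panel")
  })
}

#' @export
print.coalescent_panel <- function(x, ...) {
  cat(sprintf("coalescent_panel: %d haplotypes (%d diploids), %d segregating sites, theta=%g\n",
              nrow(x$haplotypes), nrow(x$haplotypes) / 2, ncol(x$haplotypes), x$theta))
  invisible(x)
}

#' Diploid genotype matrix of a coalescent panel
#'
#' @param panel a `coalescent_panel`.
#' @return integer matrix individuals x sites with alt-allele counts 0/1/2;
#'   rownames are individual ids and `attr(,"pops")` maps them to populations.
#' @export
panel_genotypes <- function(panel) {
  stopifnot(inherits(panel, "coalescent_panel"))
  H <- panel$haplotypes
  n_ind <- nrow(H) / 2
  G <- H[seq(1, nrow(H), by = 2), , drop = FALSE] +
       H[seq(2, nrow(H), by = 2), , drop = FALSE]
  rownames(G) <- sprintf("ind%02d", seq_len(n_ind))
  attr(G, "pops") <- setNames(panel$pop_labels, rownames(G))
  G
}

#' Assign concrete ref/alt alleles to panel sites
#'
#' The coalescent panel is binary; this maps site k to a reference allele
#' (the base of `reference` at the site's position when given, otherwise a
#' random base) and an alternate allele drawn uniformly among the three
#' alternatives.
#'
#' @param panel a `coalescent_panel`.
#' @param reference optional DNA string providing the reference alleles.
#' @param seed integer seed.
#' @return data.frame with `chrom`, `pos`, `ref`, `alt`, `is_transversion`.
#' @export
allele_map <- function(panel, reference = NULL, seed) {
  stopifnot(inherits(panel, "coalescent_panel"))
  .check_seed(seed)
  withr::with_seed(seed, {
    pos <- panel$positions
    if (!is.null(reference)) {
      if (max(pos, 0) > nchar(reference))
        stop("panel positions exceed the reference length", call. = FALSE)
      refb <- strsplit(reference, "", fixed = TRUE)[[1]][pos]
    } else {
      refb <- sample(.BASES, length(pos), replace = TRUE)
    }
    altb <- vapply(refb, function(x) sample(setdiff(.BASES, x), 1),
                   character(1), USE.NAMES = FALSE)
    data.frame(chrom = "chr1", pos = pos, ref = refb, alt = altb,
               is_transversion = is_transversion(refb, altb),
               stringsAsFactors = FALSE)
  })
}

#' Overlay a panel haplotype onto a reference sequence
#'
#' Substitutes the alternate allele at every site where haplotype
#' `hap_index` carries the derived allele, yielding the genome of one
#' chromosome of a simulated individual.
#'
#' @param reference DNA string (the panel's positions must fit inside it).
#' @param panel a `coalescent_panel`.
#' @param hap_index haplotype row (1-based).
#' @param amap output of [allele_map()] for this panel/reference.
#' @return DNA string of the same length as `reference`.
#' @export
apply_haplotype <- function(reference, panel, hap_index, amap) {
  stopifnot(inherits(panel, "coalescent_panel"))
  if (hap_index < 1 || hap_index > nrow(panel$haplotypes))
    stop("`hap_index` out of range", call. = FALSE)
  chars <- strsplit(reference, "", fixed = TRUE)[[1]]
  if (max(panel$positions, 0) > length(chars))
    stop("panel positions exceed the reference length", call. = FALSE)
  der <- panel$haplotypes[hap_index, ] == 1L
  chars[amap$pos[der]] <- amap$alt[der]
  paste(chars, collapse = "")
}

# damage on one read (chars in sequencing orientation); returns chars + 0-based hit offsets
.apply_damage <- function(chars, dm) {
  l <- length(chars)
  off5 <- seq_len(l) - 1L
  off3 <- rev(off5)
  if (dm$library_mode == "double_stranded") {
    p5 <- dm$delta5 * exp(-dm$decay * off5)
    p3 <- dm$delta3 * exp(-dm$decay * off3)
    u <- runif(l)
    ct <- chars == "C" & u < p5
    ga <- chars == "G" & u < p3
    chars[ct] <- "T"
    chars[ga] <- "A"
    hits <- which(ct | ga) - 1L
  } else {
    p <- 1 - (1 - dm$delta5 * exp(-dm$decay * off5)) *
             (1 - dm$delta3 * exp(-dm$decay * off3))
    ct <- chars == "C" & runif(l) < p
    chars[ct] <- "T"
    hits <- which(ct) - 1L
  }
  list(chars = chars, hits = hits)
}

#' Simulate damaged ancient DNA reads from a source genome
#'
#' Fragments are drawn uniformly along `source` with lengths from the
#' fragment model, emitted from either strand with probability 1/2 (reverse
#' strand reads are reverse-complemented), deaminated per the damage model in
#' sequencing orientation, and then subjected to uniform sequencing error.
#' Full provenance truth (source interval, strand, damage-altered offsets) is
#' retained for every read.
#'
#' @param source DNA string; use [apply_haplotype()] first to emit reads from
#'   a particular simulated individual's chromosome.
#' @param n_reads number of reads (> 0).
#' @param fragment_model a [fragment_model()].
#' @param damage_model a [damage_model()].
#' @param error_rate uniform per-base sequencing error in \[0, 0.1).
#' @param seed integer seed.
#' @param species,individual,haplotype provenance labels stored with each read.
#' @return an `ancient_reads` data.frame with columns `id`, `seq`, `species`,
#'   `individual`, `haplotype`, `start` (0-based), `end` (exclusive),
#'   `strand`, and a list column `damage` of 0-based read offsets.
#' @export
simulate_ancient_reads <- function(source, n_reads, fragment_model = sedna::fragment_model(),
                                   damage_model = sedna::damage_model(),
                                   error_rate = 0.001, seed,
                                   species = "A", individual = "ind1",
                                   haplotype = NA_integer_) {
  if (n_reads <= 0) stop("`n_reads` must be > 0", call. = FALSE)
  if (error_rate < 0 || error_rate >= 0.1)
    stop("`error_rate` must lie in [0, 0.1)", call. = FALSE)
  L <- nchar(source)
  if (L <= fragment_model$min_len)
    stop("source shorter than the minimum fragment length", call. = FALSE)
  .check_seed(seed)
  withr::with_seed(seed, {
    len <- pmin(.draw_fragment_lengths(n_reads, fragment_model), L)
    start <- floor(runif(n_reads) * (L - len + 1)) + 1L  # 1-based
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    frag <- substring(source, start, start + len - 1L)
    frag[strand == "-"] <- revcomp(frag[strand == "-"])
    seqs <- character(n_reads)
    damage <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      ch <- strsplit(frag[i], "", fixed = TRUE)[[1]]
      d <- .apply_damage(ch, damage_model)
      ch <- d$chars
      if (error_rate > 0) {
        err <- which(runif(len[i]) < error_rate)
        if (length(err))
          ch[err] <- vapply(ch[err], function(x) sample(setdiff(.BASES, x), 1),
                            character(1), USE.NAMES = FALSE)
      }
      seqs[i] <- paste(ch, collapse = "")
      damage[[i]] <- d$hits
    }
    out <- data.frame(id = sprintf("%s_r%05d", species, seq_len(n_reads)),
                      seq = seqs, species = species, individual = individual,
                      haplotype = haplotype,
                      start = start - 1L, end = start - 1L + len,
                      strand = strand, stringsAsFactors = FALSE)
    out$damage <- damage
    class(out) <- c("ancient_reads", "data.frame")
    out
  })
}

#' Mix two read sets into one shuffled set with provenance truth
#'
#' Read ids colliding between the two sets are renamed (suffix `_b`) before
#' the shuffled union is formed; the provenance table maps every emitted read
#' id to its true species exactly once.
#'
#' @param set_a,set_b `ancient_reads` data.frames (`set_b` may be empty).
#' @param seed integer seed controlling the shuffle.
#' @return list with `reads` (shuffled `ancient_reads`) and `provenance`
#'   (data.frame `read_id`, `species`, `source_set`).
#' @export
mix_read_sets <- function(set_a, set_b, seed) {
  .check_seed(seed)
  if (nrow(set_b) > 0) {
    clash <- set_b$id %in% set_a$id
    set_b$id[clash] <- paste0(set_b$id[clash], "_b")
  }
  merged <- rbind(set_a, set_b)
  prov <- data.frame(read_id = merged$id,
                     species = merged$species,
                     source_set = rep(c("a", "b"), c(nrow(set_a), nrow(set_b))),
                     stringsAsFactors = FALSE)
  withr::with_seed(seed, {
    ord <- sample.int(nrow(merged))
    merged <- merged[ord, , drop = FALSE]
    rownames(merged) <- NULL
    class(merged) <- c("ancient_reads", "data.frame")
    list(reads = merged, provenance = prov)
  })
}

#' Write reads as FASTQ (Phred+33, constant quality)
#'
#' @param reads an `ancient_reads` data.frame (or any data.frame with `id`
#'   and `seq`).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq")
  invisible(path)
}

#' Read a FASTQ file into a minimal read table
#'
#' @param path FASTQ file.
#' @return data.frame with `id` and `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(id = names(x), seq = as.character(x), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Write a FASTA file
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA file.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Serialise a coalescent panel to VCF v4.2 text
#'
#' One record per segregating site with GT fields 0/0, 0/1 or 1/1, the site
#' allele number `AN` (2 x non-missing individuals) and a constant mapping
#' quality annotation `MQ`. The output round-trips losslessly through
#' [read_vcf_panel()].
#'
#' @param panel a `coalescent_panel`.
#' @param amap an [allele_map()] for the panel.
#' @param path optional output file; when `NULL` the lines are returned.
#' @param mq mapping-quality annotation written to every record.
#' @return character vector of VCF lines (invisibly when `path` is given).
#' @export
panel_to_vcf <- function(panel, amap, path = NULL, mq = 60) {
  stopifnot(inherits(panel, "coalescent_panel"))
  G <- panel_genotypes(panel)
  if (nrow(amap) != ncol(G) || any(amap$pos != panel$positions))
    stop("allele map does not match the panel sites", call. = FALSE)
  if (any(amap$ref == amap$alt) || !all(c(amap$ref, amap$alt) %in% .BASES))
    stop("malformed allele map: ref/alt must be distinct ACGT bases", call. = FALSE)
  n_ind <- nrow(G)
  an <- 2L * colSums(!is.na(G))
  gt_code <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=chr1,length=%d>", as.integer(panel$chrom_length)),
    '##INFO=<ID=AN,Number=1,Type=Integer,Description="Total number of alleles in called genotypes">',
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="Mapping quality annotation">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            rownames(G)), collapse = "\t"))
  body <- vapply(seq_len(ncol(G)), function(s) {
    gts <- ifelse(is.na(G[, s]), "./.", gt_code[G[, s] + 1L])
    paste(c("chr1", amap$pos[s], ".", amap$ref[s], amap$alt[s], ".", "PASS",
            sprintf("AN=%d;MQ=%g", an[s], mq), "GT", gts), collapse = "\t")
  }, character(1))
  lines <- c(header, body)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Read a VCF genotype panel
#'
#' Ingests a VCF v4.2 file (as written by [panel_to_vcf()] or by external
#' callers) into the site table + genotype matrix pair used by the popgen
#' stage.
#'
#' @param path VCF file.
#' @return a `genotype_panel`: list with `sites` (data.frame `chrom`, `pos`,
#'   `ref`, `alt`, `mq`, `an`, `is_transversion`) and `genotypes`
#'   (samples x sites matrix of alt-allele counts, NA = missing).
#' @export
read_vcf_panel <- function(path) {
  v <- VariantAnnotation::readVcf(path, genome = "synthetic")
  rr <- SummarizedExperiment::rowRanges(v)
  ref <- as.character(VariantAnnotation::ref(v))
  altl <- VariantAnnotation::alt(v)
  alt <- vapply(seq_along(altl), function(i) as.character(altl[[i]][1]), character(1))
  info <- VariantAnnotation::info(v)
  gt <- VariantAnnotation::geno(v)$GT
  codes <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  codes[gt %in% c("0/0", "0|0")] <- 0L
  codes[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  codes[gt %in% c("1/1", "1|1")] <- 2L
  G <- t(codes)
  rownames(G) <- colnames(gt)
  sites <- data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
                      pos = BiocGenerics::start(rr),
                      ref = ref, alt = alt,
                      mq = as.numeric(info$MQ %||% rep(NA_real_, length(ref))),
                      an = as.integer(info$AN %||% (2L * colSums(!is.na(G)))),
                      is_transversion = is_transversion(ref, alt),
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(sites = sites, genotypes = G), class = "genotype_panel")
}

#' Simulate an infinite-sites multiple sequence alignment on a known tree
#'
#' Evolves a root sequence down a rooted tree, placing a fixed number of
#' substitutions on every branch, each at a previously unmutated column
#' (no homoplasy), so that every variant column maps back to exactly one
#' branch. Optionally restricted to transversion substitutions so the
#' transversion-only site filters retain every simulated variant.
#'
#' @param tree a rooted `ape::phylo`.
#' @param length alignment length in columns.
#' @param mutations_per_branch substitutions placed on each branch.
#' @param seed integer seed.
#' @param transversions_only restrict substitutions to transversions.
#' @return list with `msa` (named character vector, one row per tip),
#'   `root` sequence, and `branch_sites` (list branch-child-node -> 0-based
#'   mutated columns).
#' @export
simulate_tree_msa <- function(tree, length, mutations_per_branch, seed,
                              transversions_only = TRUE) {
  .check_seed(seed)
  n_edge <- nrow(tree$edge)
  if (n_edge * mutations_per_branch > length)
    stop("alignment too short for the requested mutations", call. = FALSE)
  withr::with_seed(seed, {
    root_seq <- sample(.BASES, length, replace = TRUE)
    cols <- sample.int(length, n_edge * mutations_per_branch)
    seqs <- vector("list", length(tree$tip.label) + tree$Nnode)
    nt <- length(tree$tip.label)
    root <- nt + 1L
    seqs[[root]] <- root_seq
    ord <- reorder(tree, "cladewise")  # parents before children
    branch_sites <- list()
    k <- 0L
    for (e in seq_len(n_edge)) {
      p <- ord$edge[e, 1]; child <- ord$edge[e, 2]
      s <- seqs[[p]]
      mut_cols <- cols[(k + 1):(k + mutations_per_branch)]
      k <- k + mutations_per_branch
      for (cc in mut_cols) {
        from <- s[cc]
        alts <- setdiff(.BASES, from)
        if (transversions_only) alts <- alts[is_transversion(rep(from, length(alts)), alts)]
        s[cc] <- sample(alts, 1)
      }
      seqs[[child]] <- s
      bid <- if (child <= nt) tree$tip.label[child] else paste0("n", child)
      branch_sites[[bid]] <- sort(mut_cols) - 1L
    }
    msa <- vapply(seq_len(nt), function(i) paste(seqs[[i]], collapse = ""), character(1))
    names(msa) <- tree$tip.label
    list(msa = msa, root = paste(root_seq, collapse = ""), branch_sites = branch_sites)
  })
}

#' Simulate a high-coverage diploid pileup from truth genotypes
#'
#' Pileup-level shortcut for the divergence stage: per site, the read depth
#' is Poisson and each read reports the alternate allele with the probability
#' implied by the true genotype and a symmetric per-base error.
#'
#' @param genotypes integer vector of alt-allele counts 0/1/2 at the sites.
#' @param mean_depth Poisson mean depth.
#' @param eps symmetric per-base error probability.
#' @param seed integer seed.
#' @return data.frame `n_ref`, `n_alt`, `n_other` per site.
#' @export
simulate_highcov_pileup <- function(genotypes, mean_depth = 25, eps = 0.01, seed) {
  .check_seed(seed)
  withr::with_seed(seed, {
    n <- length(genotypes)
    depth <- rpois(n, mean_depth)
    p_alt <- c(eps, 0.5, 1 - eps)[genotypes + 1L]
    n_alt <- rbinom(n, depth, p_alt)
    data.frame(n_ref = depth - n_alt, n_alt = n_alt, n_other = 0L)
  })
}
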