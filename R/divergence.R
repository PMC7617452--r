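# ---------------------------------------------------------------------------
# divergence: the heterozygosity-conditioned derived-allele-fraction
# statistic and its coalescent one-third null.
#
# At sites heterozygous in a high-coverage individual, the fraction of
# single-allele (pseudo-haploid) calls in a second sample matching the
# alternate allele has expectation 1/2 for the same individual, 1/3 for a
# same-population sample, and decreases with population divergence.
# ---------------------------------------------------------------------------

#' Call filtered heterozygous sites in a high-coverage sample
#'
#' Maximum-likelihood diploid genotype over \{RR, RA, AA\} with a symmetric
#' per-base error `eps`; the call quality is the Phred-scaled likelihood
#' margin over the runner-up genotype. Retains only sites that are called
#' heterozygous with call quality > `min_call_qual`, mapping quality
#' > `min_mq`, depth within `depth_range` (inclusive), and (optionally)
#' transversion ref/alt pairs.
#'
#' @param counts data.frame with `n_ref`, `n_alt` and optionally `n_other`
#'   per site (e.g. from [simulate_highcov_pileup()] or an external pileup).
#' @param sites site table with `pos`, `ref`, `alt` and a per-site `mq`
#'   mapping-quality annotation.
#' @param min_call_qual strict call-quality threshold (default 20).
#' @param min_mq strict mapping-quality threshold (default 25).
#' @param depth_range inclusive depth window (default 15..40).
#' @param transversions_only keep transversion sites only (default TRUE).
#' @param eps symmetric per-base error in (0, 0.5).
#' @return a `het_sites` data.frame: `pos`, `ref`, `alt`, `depth`,
#'   `call_qual` for every retained site.
#' @export
call_het_sites <- function(counts, sites, min_call_qual = 20, min_mq = 25,
                           depth_range = c(15, 40), transversions_only = TRUE,
                           eps = 0.01) {
  if (eps <= 0 || eps >= 0.5) stop("`eps` must lie in (0, 0.5)", call. = FALSE)
  stopifnot(nrow(counts) == nrow(sites))
  nr <- counts$n_ref
  na_ <- counts$n_alt
  no <- counts$n_other %||% rep(0L, nrow(counts))
  depth <- nr + na_ + no
  ll <- cbind(RR = nr * log(1 - eps) + na_ * log(eps),
              RA = (nr + na_) * log(0.5),
              AA = nr * log(eps) + na_ * log(1 - eps))
  best <- max.col(ll, ties.method = "first")
  ord <- t(apply(ll, 1, sort, decreasing = TRUE))
  call_qual <- 10 / log(10) * (ord[, 1] - ord[, 2])
  keep <- best == 2L &
    call_qual > min_call_qual &
    sites$mq > min_mq &
    depth >= depth_range[1] & depth <= depth_range[2] &
    sites$ref != sites$alt
  if (transversions_only) keep <- keep & is_transversion(sites$ref, sites$alt)
  out <- data.frame(pos = sites$pos[keep], ref = sites$ref[keep],
                    alt = sites$alt[keep], depth = depth[keep],
                    call_qual = call_qual[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "filters") <- list(min_call_qual = min_call_qual, min_mq = min_mq,
                               depth_range = depth_range,
                               transversions_only = transversions_only,
                               eps = eps)
  class(out) <- c("het_sites", "data.frame")
  out
}

#' Derived-allele fraction of a low-coverage sample at heterozygous sites
#'
#' Applies the mandatory single-read-only pseudo-haploid rule: a site is
#' observed when exactly one filtered read overlaps it and that read's base
#' is the ref or the alt allele (third alleles are missing). The statistic
#' is n_alt / n_observed with an exact 95% binomial confidence interval.
#'
#' @param het_sites a `het_sites` data.frame for the high-coverage
#'   individual.
#' @param pileup named list position -> character vector of read bases for
#'   the low-coverage sample (e.g. [pileup_bases()] at `het_sites$pos`).
#' @param seed unused (the single-read rule is deterministic); accepted for
#'   interface symmetry with the random-read caller.
#' @return a `derived_fraction`: list with `n_observed`, `n_alt`,
#'   `fraction`, `ci` (exact 95%), `status` (`"ok"` or `"undefined"` when no
#'   site is observed).
#' @export
derived_allele_fraction <- function(het_sites, pileup, seed = NULL) {
  idx <- match(as.integer(names(pileup)), het_sites$pos)
  if (anyNA(idx))
    stop("pileup positions absent from the heterozygous site set", call. = FALSE)
  n_obs <- 0L
  n_alt <- 0L
  for (k in seq_along(pileup)) {
    bases <- pileup[[k]]
    if (length(bases) != 1L) next
    i <- idx[k]
    if (bases == het_sites$alt[i]) { n_obs <- n_obs + 1L; n_alt <- n_alt + 1L }
    else if (bases == het_sites$ref[i]) n_obs <- n_obs + 1L
  }
  if (n_obs == 0L) {
    return(structure(list(n_observed = 0L, n_alt = 0L, fraction = NA_real_,
                          ci = c(NA_real_, NA_real_), status = "undefined"),
                     class = "derived_fraction"))
  }
  ci <- as.numeric(binom.test(n_alt, n_obs)$conf.int)
  structure(list(n_observed = n_obs, n_alt = n_alt, fraction = n_alt / n_obs,
                 ci = ci, status = "ok"),
            class = "derived_fraction")
}

#' @export
print.derived_fraction <- function(x, ...) {
  if (x$status == "undefined") cat("derived_fraction: undefined (no observed sites)\n")
  else cat(sprintf("derived_fraction: %d/%d = %.3f [%.3f, %.3f]\n",
                   x$n_alt, x$n_observed, x$fraction, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Coalescent same-population null of the derived-allele fraction
#'
#' Simulates panmictic genome-wide panels (`n_loci` unlinked loci per
#' replicate), designates one diploid as the high-coverage truth, samples
#' one allele of a second diploid at the first's heterozygous sites, and
#' averages the fraction matching the derived allele. The closed-form
#' three-lineage value is 1/3: conditional on the first two lineages
#' differing, the third carries the derived allele with probability 1/3.
#'
#' The 1/3 value is a ratio of expectations (matches over het sites), so it
#' is recovered by pooling sites across many independent genealogies; on a
#' single non-recombining genealogy the per-replicate ratio is biased low
#' because site-rich genealogies have systematically lower fractions. Each
#' replicate therefore pools `n_loci` unlinked loci, as a genome does.
#'
#' @param theta genome-wide scaled mutation rate per replicate (split
#'   evenly over the loci); the expected number of heterozygous sites per
#'   replicate individual is `theta`.
#' @param n_diploids diploids per panel (>= 2).
#' @param n_replicates number of replicate panels (>= 1).
#' @param seed integer seed.
#' @param n_loci unlinked loci per replicate (default 100).
#' @return list with `expectation` (mean fraction over replicates),
#'   `mc_error` (standard error over replicates), `per_replicate`,
#'   `n_het_total`, `pooled_fraction`.
#' @export
null_expectation_same_pop <- function(theta, n_diploids, n_replicates, seed,
                                      n_loci = 100) {
  stopifnot(n_diploids >= 2, n_replicates >= 1)
  .check_seed(seed)
  fracs <- numeric(n_replicates)
  n_het <- integer(n_replicates)
  n_match <- integer(n_replicates)
  withr::with_seed(seed, {
    for (r in seq_len(n_replicates)) {
      panel <- simulate_multilocus_panel(n_loci, n_diploids, 1, 0,
                                         theta / n_loci,
                                         seed = sample.int(2^30, 1))
      H <- panel$haplotypes
      het <- which(H[1, ] != H[2, ])          # individual 1 heterozygous
      pick <- sample(3:4, length(het), replace = TRUE)  # one allele of individual 2
      obs <- H[cbind(pick, het)]
      n_het[r] <- length(het)
      n_match[r] <- sum(obs == 1L)
      fracs[r] <- if (length(het)) n_match[r] / length(het) else NA_real_
    }
  })
  list(expectation = mean(fracs, na.rm = TRUE),
       mc_error = sd(fracs, na.rm = TRUE) / sqrt(sum(!is.na(fracs))),
       per_replicate = fracs, n_het_total = sum(n_het),
       pooled_fraction = sum(n_match) / sum(n_het))
}

#' End-to-end divergence scan over population split times
#'
#' For each split time: simulates a two-population coalescent panel on a
#' reference chromosome, takes the high-coverage individual's heterozygous
#' transversion sites from the truth genotypes of population 1, simulates
#' damaged low-coverage reads from one individual of population 2, maps them
#' end-to-end to the reference, applies the alignment filters, and computes
#' the single-read derived-allele fraction. Replicate counts are pooled per
#' split time. Deeper splits share fewer polymorphisms, so the fraction
#' decreases from the one-third null at split 0.
#'
#' @param split_times numeric vector of scaled split times; must contain 0
#'   and at least one more value.
#' @param n_diploids_per_pop diploids per population (default 5).
#' @param theta genome-wide scaled mutation rate (default 600), split over
#'   `n_loci` unlinked windows laid side by side on the reference — the
#'   reference emulates a concatenation of distant genomic windows, not one
#'   linked region, so replicate fractions pool independent genealogies.
#' @param n_loci number of unlinked windows (default 24).
#' @param ref_length reference length in bp (default 12000).
#' @param n_replicates replicates per split time (default 10).
#' @param coverage target read coverage of the low-coverage sample
#'   (default 0.5x, i.e. mostly single-read sites).
#' @param fragment_model,damage_model read simulation models.
#' @param error_rate sequencing error rate.
#' @param max_mismatch_rate,min_map_score,min_len mapper/filter settings.
#' @param seed integer seed.
#' @return a `divergence_scan` data.frame: `split_time`, `n_observed`,
#'   `n_alt`, `fraction`, `se` (binomial).
#' @export
divergence_scan <- function(split_times, n_diploids_per_pop = 5, theta = 600,
                            n_loci = 24, ref_length = 12000, n_replicates = 10,
                            coverage = 0.5,
                            fragment_model = sedna::fragment_model(),
                            damage_model = sedna::damage_model(delta5 = 0.2, delta3 = 0.2),
                            error_rate = 0.002, max_mismatch_rate = 0.2,
                            min_map_score = 25, min_len = 35, seed) {
  if (length(split_times) < 2 || !any(split_times == 0))
    stop("`split_times` must contain 0 and at least one further value", call. = FALSE)
  .check_seed(seed)
  n_reads <- max(10L, round(coverage * ref_length / fragment_model$mean_len))
  res <- lapply(split_times, function(st) c(n_obs = 0L, n_alt = 0L))
  names(res) <- as.character(split_times)
  withr::with_seed(seed, {
    # paired design: the same per-replicate seeds are reused for every split
    # time (common random numbers), so split-time contrasts are not swamped
    # by between-replicate genealogy noise
    subs <- matrix(sample.int(2^30, 4L * n_replicates), nrow = n_replicates)
    for (st_i in seq_along(split_times)) {
      st <- split_times[st_i]
      for (r in seq_len(n_replicates)) {
        sub <- subs[r, ]
        reference <- random_dna(ref_length, sub[1])
        panel <- simulate_multilocus_panel(n_loci, n_diploids_per_pop, 2, st,
                                           theta / n_loci, seed = sub[2],
                                           chrom_length = ref_length %/% n_loci)
        amap <- allele_map(panel, reference, seed = sub[3])
        # high-coverage truth: first diploid of pop 1
        het <- which(panel$haplotypes[1, ] != panel$haplotypes[2, ] &
                       amap$is_transversion)
        if (!length(het)) next
        het_sites <- data.frame(pos = amap$pos[het], ref = amap$ref[het],
                                alt = amap$alt[het], depth = NA_integer_,
                                call_qual = NA_real_)
        class(het_sites) <- c("het_sites", "data.frame")
        # low-coverage reads: first diploid of pop 2, both chromosomes
        h1 <- 2L * n_diploids_per_pop + 1L
        reads <- NULL
        for (hap in c(h1, h1 + 1L)) {
          src <- apply_haplotype(reference, panel, hap, amap)
          rr <- simulate_ancient_reads(src, ceiling(n_reads / 2),
                                       fragment_model, damage_model,
                                       error_rate, seed = sub[4] + hap,
                                       species = sprintf("h%d", hap),
                                       haplotype = hap)
          reads <- if (is.null(reads)) rr else rbind(reads, rr)
        }
        aln <- map_reads_end_to_end(reads, c(ref = reference),
                                    max_mismatch_rate = max_mismatch_rate,
                                    min_len = min_len, damage_tolerant = TRUE)
        aln <- filter_alignments(aln, min_map_score = min_map_score,
                                 min_len = min_len)
        pu <- pileup_bases(aln, het_sites$pos)
        df <- derived_allele_fraction(het_sites, pu)
        res[[st_i]]["n_obs"] <- res[[st_i]]["n_obs"] + df$n_observed
        res[[st_i]]["n_alt"] <- res[[st_i]]["n_alt"] + df$n_alt
      }
    }
  })
  n_obs <- vapply(res, `[`, numeric(1), "n_obs")
  n_alt <- vapply(res, `[`, numeric(1), "n_alt")
  frac <- ifelse(n_obs > 0, n_alt / n_obs, NA_real_)
  out <- data.frame(split_time = split_times, n_observed = n_obs,
                    n_alt = n_alt, fraction = frac,
                    se = ifelse(n_obs > 0, sqrt(frac * (1 - frac) / n_obs), NA_real_),
                    row.names = NULL)
  class(out) <- c("divergence_scan", "data.frame")
  out
}
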