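# ---------------------------------------------------------------------------
# popgen: nuclear-panel stage. Site filters, pseudo-haploid calling,
# rescaled Hamming distances, neighbor joining, sparse-sample PCA
# projection, f4 statistics with block jackknife.
# ---------------------------------------------------------------------------

#' Filter a site panel on mapping quality, allele number and biallelism
#'
#' Strict inequalities per the pipeline's convention: sites are kept when
#' MQ > `min_mq` AND AN > `min_an` AND (optionally) biallelic. AN is
#' recomputed from the genotype matrix as 2 x non-missing diploids so the
#' filter cannot drift from the data.
#'
#' @param panel a `genotype_panel` (list of `sites` + `genotypes`, e.g. from
#'   [read_vcf_panel()]).
#' @param min_mq mapping-quality threshold, strict (default 20).
#' @param min_an allele-number threshold, strict (default 150, i.e. at
#'   least 76 fully called diploids).
#' @param biallelic_only require distinct single-base ref/alt.
#' @return filtered `genotype_panel`; `attr(,"removed")` counts removals by
#'   reason.
#' @export
filter_site_panel <- function(panel, min_mq = 20, min_an = 150,
                              biallelic_only = TRUE) {
  sites <- panel$sites
  G <- panel$genotypes
  an <- 2L * as.integer(colSums(!is.na(G)))
  sites$an <- an
  bad_mq <- !(sites$mq > min_mq) | is.na(sites$mq)
  bad_an <- !(an > min_an)
  bad_bi <- if (biallelic_only)
    !(sites$ref != sites$alt & sites$ref %in% .BASES & sites$alt %in% .BASES)
  else rep(FALSE, nrow(sites))
  keep <- !(bad_mq | bad_an | bad_bi)
  out <- structure(list(sites = sites[keep, , drop = FALSE],
                        genotypes = G[, keep, drop = FALSE]),
                   class = "genotype_panel")
  rownames(out$sites) <- NULL
  attr(out, "removed") <- c(mq = sum(bad_mq), an = sum(bad_an),
                            not_biallelic = sum(bad_bi))
  out
}

#' Pseudo-haploid call for one low-coverage sample
#'
#' Represents the sample at each panel site by a single sampled allele:
#' `random_read` picks one uniformly chosen read per covered site;
#' `single_read_only` calls only where exactly one read overlaps the site
#' (the guard against amplification bias used by the divergence statistic)
#' and is missing elsewhere. The chosen base must equal the site's ref or
#' alt allele, otherwise the call is missing.
#'
#' @param pileup named list, position -> character vector of read bases
#'   (e.g. from [pileup_bases()]); names must be positions present in the
#'   panel.
#' @param sites site table with `pos`, `ref`, `alt`.
#' @param mode `"random_read"` or `"single_read_only"`.
#' @param seed integer seed (used by `random_read`).
#' @return a `pseudo_haploid` integer vector over the panel sites with
#'   values 0 (ref), 1 (alt) or NA, and attributes `mode` and `seed`.
#' @export
pseudo_haploid_call <- function(pileup, sites, mode = c("random_read", "single_read_only"),
                                seed = 1L) {
  mode <- match.arg(mode)
  .check_seed(seed)
  pos <- as.integer(names(pileup))
  if (anyNA(pos) || !all(pos %in% sites$pos))
    stop("pileup positions absent from the site panel: ",
         paste(setdiff(pos, sites$pos), collapse = ", "), call. = FALSE)
  calls <- rep(NA_integer_, nrow(sites))
  idx <- match(pos, sites$pos)
  withr::with_seed(seed, {
    for (k in seq_along(pileup)) {
      bases <- pileup[[k]]
      if (!length(bases)) next
      if (mode == "single_read_only") {
        if (length(bases) != 1L) next
        b <- bases
      } else {
        b <- bases[sample.int(length(bases), 1)]
      }
      i <- idx[k]
      if (b == sites$ref[i]) calls[i] <- 0L
      else if (b == sites$alt[i]) calls[i] <- 1L
    }
  })
  structure(calls, mode = mode, seed = seed, class = "pseudo_haploid")
}

#' Merge diploid genotypes with pseudo-haploid samples
#'
#' Pseudo-haploid codes are doubled to \{0, 2\} so they live on the diploid
#' dosage scale. Note the known inflation this creates: a pseudo-haploid
#' sample re-drawn independently from the same individual has positive
#' distance to itself at heterozygous sites.
#'
#' @param G diploid matrix samples x sites (codes 0/1/2, NA missing).
#' @param pseudo named list of `pseudo_haploid` vectors over the same sites.
#' @return combined matrix with the pseudo-haploid rows appended.
#' @export
merge_pseudo_haploid <- function(G, pseudo) {
  stopifnot(is.list(pseudo), !is.null(names(pseudo)))
  P <- do.call(rbind, lapply(pseudo, function(v) 2L * as.integer(v)))
  rownames(P) <- names(pseudo)
  rbind(G, P)
}

#' Pairwise Hamming distance matrix with flat-missing rescaling
#'
#' Raw distance between two samples is the sum of |dosage differences| over
#' sites non-missing in both; with `rescale_missing` each pair distance is
#' multiplied by (total sites / pair-observed sites), putting sparse
#' (ancient) samples on the same scale as the rest of the matrix. The
#' rescaled distance is an unbiased estimator of the no-missing distance
#' under missing-completely-at-random thinning.
#'
#' @param G matrix samples x sites of dosage codes (0/1/2 diploid, 0/2
#'   doubled pseudo-haploid), NA missing.
#' @param rescale_missing apply the flat-missing rescale (default TRUE).
#' @return a `hamming_dist`: list with `dist` (matrix), `nobs` (pair
#'   observed-site counts), `rescaled`, `total_sites`, `undefined_pairs`
#'   (pairs with zero joint observations, distance NA).
#' @export
hamming_distance_matrix <- function(G, rescale_missing = TRUE) {
  n <- nrow(G)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  S <- ncol(G)
  D <- matrix(0, n, n, dimnames = list(rownames(G), rownames(G)))
  NOBS <- matrix(S, n, n, dimnames = dimnames(D))
  undef <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(G[i, ]) & !is.na(G[j, ])
      m <- sum(ok)
      NOBS[i, j] <- NOBS[j, i] <- m
      if (m == 0) {
        D[i, j] <- D[j, i] <- NA_real_
        undef <- c(undef, paste(rownames(G)[c(i, j)], collapse = ":"))
        next
      }
      raw <- sum(abs(G[i, ok] - G[j, ok]))
      D[i, j] <- D[j, i] <- if (rescale_missing) raw * S / m else raw
    }
  }
  structure(list(dist = D, nobs = NOBS, rescaled = rescale_missing,
                 total_sites = S, undefined_pairs = undef),
            class = "hamming_dist")
}

#' Neighbor-joining tree (Saitou-Nei)
#'
#' Standard Q-criterion agglomeration; negative branch lengths are clamped
#' to zero with a warning. Input order does not affect the unrooted
#' topology.
#'
#' @param dm a `hamming_dist` or a symmetric numeric matrix with dimnames.
#' @return an unrooted `ape::phylo` with branch lengths.
#' @export
neighbor_joining <- function(dm) {
  D <- if (inherits(dm, "hamming_dist")) dm$dist else as.matrix(dm)
  if (anyNA(D)) stop("undefined distances; cannot build a tree", call. = FALSE)
  n <- nrow(D)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  labs <- rownames(D) %||% paste0("t", seq_len(n))
  frag <- labs                       # newick fragment per active cluster
  clamped <- FALSE
  cl <- function(x) { if (x < 0) clamped <<- TRUE; max(x, 0) }
  while (nrow(D) > 3) {
    r <- nrow(D)
    Rs <- rowSums(D)
    Q <- (r - 2) * D - outer(Rs, Rs, "+")
    diag(Q) <- Inf
    ij <- which(Q == min(Q), arr.ind = TRUE)
    ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE][1, ]  # deterministic tie-break
    i <- min(ij); j <- max(ij)
    li <- D[i, j] / 2 + (Rs[i] - Rs[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    li <- cl(li); lj <- cl(lj)
    newfrag <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], li, frag[j], lj)
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    frag <- c(frag[keep], newfrag)
  }
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frag[1], cl(la), frag[2], cl(lb), frag[3], cl(lc))
  if (clamped) warning("negative NJ branch length(s) clamped to 0")
  ape::read.tree(text = nwk)
}

#' Fit a PCA on a modern panel and project sparse ancient samples
#'
#' Sites are centred by the modern mean dosage and scaled by
#' sqrt(p(1-p)) with p the modern alternate-allele frequency; monomorphic
#' sites and sites whose modern missing rate exceeds `missing_cap` are
#' dropped. The modern scores come from the singular value decomposition of
#' the standardized matrix; each ancient sample (arbitrarily sparse, but not
#' all-missing) is projected by least squares of its standardized
#' non-missing entries against the loadings. An optional per-component
#' shrinkage multiplier is applied to ancient projections only (default
#' off; the reproducible core is plain least squares).
#'
#' @param modern matrix samples x sites of diploid dosages 0/1/2 (NA
#'   missing).
#' @param ancients named list of `pseudo_haploid` vectors (codes 0/1/NA,
#'   doubled internally) or dosage vectors on the 0..2 scale.
#' @param k number of components (default 2).
#' @param missing_cap maximum modern per-site missing rate (default 0.2).
#' @param shrinkage optional numeric vector of length `k` multiplying the
#'   ancient projections.
#' @return list with `model` (center, scale, loadings, eigenvalues, modern
#'   `scores`, `kept_sites`) and `projections` (ancients x k).
#' @export
pca_fit_project <- function(modern, ancients = list(), k = 2,
                            missing_cap = 0.2, shrinkage = NULL) {
  miss <- colMeans(is.na(modern))
  p <- colMeans(modern, na.rm = TRUE) / 2
  keep <- miss <= missing_cap & p > 0 & p < 1 & !is.na(p)
  M <- modern[, keep, drop = FALSE]
  p <- p[keep]
  ctr <- 2 * p
  scl <- sqrt(p * (1 - p))
  X <- sweep(sweep(M, 2, ctr, "-"), 2, scl, "/")
  X[is.na(X)] <- 0
  sv <- svd(X, nu = k, nv = k)
  loadings <- sv$v
  scores <- X %*% loadings
  eig <- sv$d^2 / (nrow(M) - 1)
  proj <- NULL
  if (length(ancients)) {
    proj <- matrix(NA_real_, length(ancients), k,
                   dimnames = list(names(ancients), NULL))
    for (a in seq_along(ancients)) {
      v <- ancients[[a]]
      dos <- if (inherits(v, "pseudo_haploid")) 2 * as.numeric(v) else as.numeric(v)
      dos <- dos[keep]
      o <- !is.na(dos)
      if (!any(o))
        stop(sprintf("ancient sample '%s' is missing at every retained site",
                     names(ancients)[a] %||% a), call. = FALSE)
      x <- (dos[o] - ctr[o]) / scl[o]
      V <- loadings[o, , drop = FALSE]
      beta <- qr.solve(crossprod(V), crossprod(V, x))
      if (!is.null(shrinkage)) beta <- beta * shrinkage
      proj[a, ] <- beta
    }
  }
  list(model = list(center = ctr, scale = scl, loadings = loadings,
                    eigenvalues = eig[seq_len(k)], scores = scores,
                    kept_sites = which(keep)),
       projections = proj)
}

#' Population allele frequencies from a genotype matrix
#'
#' @param G matrix samples x sites of dosages 0/1/2 (NA missing).
#' @param pops character vector of population labels per sample (defaults to
#'   `attr(G, "pops")`).
#' @return matrix sites x populations of alternate-allele frequencies (NA
#'   where a population has no called genotype).
#' @export
pop_freqs <- function(G, pops = attr(G, "pops")) {
  stopifnot(!is.null(pops), length(pops) == nrow(G))
  out <- sapply(unique(pops), function(p) {
    colMeans(G[pops == p, , drop = FALSE], na.rm = TRUE) / 2
  })
  out[is.nan(out)] <- NA_real_
  out
}

#' f4 statistic with weighted block jackknife
#'
#' estimate = mean over usable sites of (pA - pB)(pC - pD); a site is usable
#' when all four populations have a defined frequency. The standard error is
#' a delete-one-block jackknife over consecutive blocks of `block_size`
#' usable sites in the input (coordinate) order, the last block possibly
#' short, with the weighted jackknife correcting for unequal block sizes.
#' Z = estimate / SE. The estimate is invariant to site order; the SE
#' changes only through block composition.
#'
#' @param freqs matrix sites x populations of allele frequencies (e.g. from
#'   [pop_freqs()]), in coordinate order.
#' @param quad character vector (A, B, C, D) naming four columns.
#' @param block_size_snps jackknife block size in usable SNPs (default 500).
#' @return an `f4_result`: list with `estimate`, `se`, `z`, `n_blocks`,
#'   `n_sites`, `quad`.
#' @export
f4_statistic <- function(freqs, quad, block_size_snps = 500) {
  stopifnot(length(quad) == 4, all(quad %in% colnames(freqs)))
  f <- freqs[, quad, drop = FALSE]
  usable <- rowSums(is.na(f)) == 0
  if (!any(usable)) stop("no usable sites for this quadruple", call. = FALSE)
  f <- f[usable, , drop = FALSE]
  d <- (f[, 1] - f[, 2]) * (f[, 3] - f[, 4])
  n <- length(d)
  est <- mean(d)
  g <- ceiling(n / block_size_snps)
  if (g < 2) {
    se <- NA_real_
  } else {
    block <- rep(seq_len(g), each = block_size_snps)[seq_len(n)]
    m <- tabulate(block, g)
    tot <- sum(d)
    loo <- vapply(seq_len(g), function(j) (tot - sum(d[block == j])) / (n - m[j]),
                  numeric(1))
    h <- n / m
    theta_J <- g * est - sum((1 - m / n) * loo)
    tau <- h * est - (h - 1) * loo
    se <- sqrt(mean((tau - theta_J)^2 / (h - 1)))
  }
  structure(list(estimate = est, se = se,
                 z = if (!is.na(se) && se > 0) est / se else NA_real_,
                 n_blocks = g, n_sites = n, quad = quad),
            class = "f4_result")
}

#' @export
print.f4_result <- function(x, ...) {
  cat(sprintf("f4(%s,%s;%s,%s) = %.6g  SE %.3g  Z %.2f  (%d sites, %d blocks)\n",
              x$quad[1], x$quad[2], x$quad[3], x$quad[4],
              x$estimate, x$se, x$z, x$n_sites, x$n_blocks))
  invisible(x)
}
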