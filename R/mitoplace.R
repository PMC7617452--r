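# ---------------------------------------------------------------------------
# mitoplace: branch-assigned transversion SNPs on a rooted tree, per-branch
# support/conflict tallies for partitioned read sets, greedy best-path
# placement. MSA columns are the universal coordinate system; the MSA
# consensus is the mapping target.
# ---------------------------------------------------------------------------

.msa_matrix <- function(msa) {
  if (inherits(msa, "DNAStringSet"))
    msa <- setNames(as.character(msa), names(msa))
  stopifnot(is.character(msa), !is.null(names(msa)))
  if (length(unique(nchar(msa))) != 1)
    stop("MSA rows must have equal length", call. = FALSE)
  m <- do.call(rbind, strsplit(toupper(msa), "", fixed = TRUE))
  rownames(m) <- names(msa)
  m
}

# branch table of a rooted tree: one row per edge, id'd by the child node
# (tip label for terminal branches, "n<node>" for internal ones)
.branch_table <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  nt <- length(tree$tip.label)
  po <- stats::reorder(tree, "postorder")
  desc <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) desc[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]
    ch <- po$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  child <- tree$edge[, 2]
  data.frame(branch_id = ifelse(child <= nt, tree$tip.label[child],
                                paste0("n", child)),
             parent_node = tree$edge[, 1], child_node = child,
             stringsAsFactors = FALSE) ->
    bt
  bt$leaves <- lapply(desc[child], sort)
  bt
}

#' Extract biallelic (optionally transversion-only) sites from an MSA
#'
#' Columns with a non-ACGT base in the designated reference row are dropped,
#' as are columns that are not exactly biallelic over the scored rows; rows
#' carrying N or a gap at a column are excluded from that column's carriers.
#' With `transversions_only`, the transition columns (A/G and C/T) are also
#' dropped, removing the substitution classes that deamination damage can
#' mimic.
#'
#' @param msa named character vector (or `DNAStringSet`) of equal-length
#'   aligned sequences over A,C,G,T,N,-.
#' @param transversions_only drop transition columns.
#' @param reference_row name of the MSA row acting as reference; must be
#'   present.
#' @return a `biallelic_sites` data.frame: `col0` (0-based column),
#'   `allele1`, `allele2` (alphabetical), `is_transversion`, and list
#'   columns `carriers1`, `carriers2` (row names carrying each allele).
#' @export
extract_biallelic_sites <- function(msa, transversions_only = FALSE,
                                    reference_row) {
  m <- .msa_matrix(msa)
  if (!reference_row %in% rownames(m))
    stop(sprintf("reference row '%s' absent from the MSA", reference_row),
         call. = FALSE)
  refrow <- m[reference_row, ]
  keep <- list()
  for (j in seq_len(ncol(m))) {
    if (!refrow[j] %in% .BASES) next
    col <- m[, j]
    scored <- col %in% .BASES
    alleles <- sort(unique(col[scored]))
    if (length(alleles) != 2) next
    tv <- is_transversion(alleles[1], alleles[2])
    if (transversions_only && !tv) next
    keep[[length(keep) + 1L]] <- list(
      col0 = j - 1L, allele1 = alleles[1], allele2 = alleles[2],
      is_transversion = tv,
      carriers1 = sort(rownames(m)[scored & col == alleles[1]]),
      carriers2 = sort(rownames(m)[scored & col == alleles[2]]))
  }
  out <- data.frame(
    col0 = vapply(keep, `[[`, integer(1), "col0"),
    allele1 = vapply(keep, `[[`, character(1), "allele1"),
    allele2 = vapply(keep, `[[`, character(1), "allele2"),
    is_transversion = vapply(keep, `[[`, logical(1), "is_transversion"),
    stringsAsFactors = FALSE)
  out$carriers1 <- lapply(keep, `[[`, "carriers1")
  out$carriers2 <- lapply(keep, `[[`, "carriers2")
  class(out) <- c("biallelic_sites", "data.frame")
  out
}

#' Plurality consensus of an MSA
#'
#' Per-column plurality base over A,C,G,T with ties broken in the fixed
#' order A < C < G < T; columns where gaps/N outnumber every base become N.
#'
#' @param msa named character vector (or `DNAStringSet`) of aligned rows.
#' @return consensus DNA string of the alignment length.
#' @export
consensus_from_msa <- function(msa) {
  m <- .msa_matrix(msa)
  if (nrow(m) == 0) stop("empty MSA", call. = FALSE)
  out <- character(ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    cnt <- vapply(.BASES, function(b) sum(col == b), integer(1))
    other <- sum(!col %in% .BASES)
    if (other > max(cnt)) {
      out[j] <- "N"
    } else {
      out[j] <- .BASES[which.max(cnt)]   # which.max takes the first = A<C<G<T
    }
  }
  paste(out, collapse = "")
}

#' Consensus from a read pileup with depth and agreement thresholds
#'
#' A base is emitted only where depth is at least `min_depth` (default 3x)
#' and the plurality base reaches `min_fraction` (default 66%) of the
#' coverage; any site failing either criterion becomes N. Monotone: raising
#' either threshold never converts an N into a base.
#'
#' @param pileup sites x 4 count matrix (columns A,C,G,T), e.g. from
#'   [pileup_counts()].
#' @param min_fraction plurality fraction threshold (default 0.66).
#' @param min_depth coverage threshold (default 3).
#' @return consensus DNA string with N at failing sites.
#' @export
consensus_from_pileup <- function(pileup, min_fraction = 0.66, min_depth = 3) {
  depth <- rowSums(pileup)
  best <- max.col(pileup, ties.method = "first")
  bestn <- pileup[cbind(seq_len(nrow(pileup)), best)]
  ok <- depth >= min_depth & bestn >= min_fraction * depth
  paste(ifelse(ok, .BASES[best], "N"), collapse = "")
}

#' Assign biallelic sites to tree branches
#'
#' A site is assigned to branch b exactly when one allele's carrier set
#' equals the leaf set of the clade below b; that allele is recorded as
#' derived. When both alleles subtend clades (a root split), the derived
#' allele is the one on the side not containing the designated outgroup.
#' Sites matching no clade are reported unassigned as `homoplasic`, or as
#' `missing_data` when rows excluded at that column (or an unscored
#' outgroup) prevent a clean match.
#'
#' @param tree a rooted `ape::phylo` whose tips cover all carriers.
#' @param sites a `biallelic_sites` data.frame.
#' @param outgroup tip label(s) of the designated outgroup.
#' @return a `branch_variant_map`: list with `assignments` (data.frame
#'   `site`, `col0`, `branch_id`, `derived`, `ancestral`), `unassigned`
#'   (data.frame `site`, `col0`, `reason`), `branches` (branch table),
#'   `outgroup`.
#' @export
assign_sites_to_branches <- function(tree, sites, outgroup) {
  bt <- .branch_table(tree)
  tips <- tree$tip.label
  if (!all(outgroup %in% tips)) stop("outgroup not in the tree", call. = FALSE)
  allc <- unique(unlist(c(sites$carriers1, sites$carriers2)))
  if (!all(allc %in% tips))
    stop("carrier leaves missing from tree: ",
         paste(setdiff(allc, tips), collapse = ", "), call. = FALSE)
  key <- vapply(bt$leaves, paste, character(1), collapse = "\r")
  asg <- list()
  una <- list()
  for (i in seq_len(nrow(sites))) {
    c1 <- sites$carriers1[[i]]
    c2 <- sites$carriers2[[i]]
    k1 <- paste(c1, collapse = "\r")
    k2 <- paste(c2, collapse = "\r")
    b1 <- match(k1, key)
    b2 <- match(k2, key)
    full <- length(c1) + length(c2) == length(tips)
    pick <- NA_integer_
    der <- NA_character_
    if (!is.na(b1) && !is.na(b2)) {
      og_in_1 <- any(outgroup %in% c1)
      og_in_2 <- any(outgroup %in% c2)
      if (og_in_1 && !og_in_2) { pick <- b2; der <- sites$allele2[i] }
      else if (og_in_2 && !og_in_1) { pick <- b1; der <- sites$allele1[i] }
      # outgroup unscored at this column: polarity undetermined
    } else if (!is.na(b1)) { pick <- b1; der <- sites$allele1[i] }
    else if (!is.na(b2)) { pick <- b2; der <- sites$allele2[i] }
    if (!is.na(pick)) {
      anc <- setdiff(c(sites$allele1[i], sites$allele2[i]), der)
      asg[[length(asg) + 1L]] <- data.frame(
        site = i, col0 = sites$col0[i], branch_id = bt$branch_id[pick],
        derived = der, ancestral = anc, stringsAsFactors = FALSE)
    } else {
      una[[length(una) + 1L]] <- data.frame(
        site = i, col0 = sites$col0[i],
        reason = if (full) "homoplasic" else "missing_data",
        stringsAsFactors = FALSE)
    }
  }
  assignments <- if (length(asg)) do.call(rbind, asg) else
    data.frame(site = integer(0), col0 = integer(0), branch_id = character(0),
               derived = character(0), ancestral = character(0))
  unassigned <- if (length(una)) do.call(rbind, una) else
    data.frame(site = integer(0), col0 = integer(0), reason = character(0))
  structure(list(assignments = assignments, unassigned = unassigned,
                 branches = bt, outgroup = outgroup, tree = tree),
            class = "branch_variant_map")
}

#' Tally per-branch support and conflict for one read set
#'
#' For each branch-assigned site covered by at least one read (alignments on
#' consensus/MSA coordinates), the plurality base across the covering reads
#' is taken (ties skip the site); the derived allele counts as support for
#' the site's branch, the ancestral allele as conflict, any other base is
#' skipped. Each site contributes at most once per read set, so deep read
#' stacks cannot dominate single-copy signal.
#'
#' @param aln `alignments` on the consensus coordinate system.
#' @param map a `branch_variant_map`.
#' @param sites the `biallelic_sites` the map was built from.
#' @param consensus_length length of the consensus sequence (coordinate
#'   bound; alignments beyond it are an error).
#' @param transversions_only restrict to transversion sites (default TRUE).
#' @return a `branch_support` data.frame: `branch_id`, `support`, `conflict`
#'   for every branch of the tree (zeros included).
#' @export
tally_branch_support <- function(aln, map, sites, consensus_length,
                                 transversions_only = TRUE) {
  if (nrow(aln) > 0 && any(aln$start + aln$aligned_length > consensus_length))
    stop("alignment coordinates exceed the consensus length", call. = FALSE)
  asg <- map$assignments
  if (transversions_only && nrow(asg) > 0)
    asg <- asg[sites$is_transversion[asg$site], , drop = FALSE]
  bt <- map$branches
  support <- setNames(integer(nrow(bt)), bt$branch_id)
  conflict <- support
  if (nrow(asg) > 0) {
    piles <- pileup_bases(aln, asg$col0 + 1L)
    for (i in seq_len(nrow(asg))) {
      bases <- piles[[i]]
      if (!length(bases)) next
      tab <- table(bases)
      winners <- names(tab)[tab == max(tab)]
      if (length(winners) != 1) next            # tie: site skipped
      b <- asg$branch_id[i]
      if (winners == asg$derived[i]) support[b] <- support[b] + 1L
      else if (winners == asg$ancestral[i]) conflict[b] <- conflict[b] + 1L
    }
  }
  out <- data.frame(branch_id = bt$branch_id, support = unname(support),
                    conflict = unname(conflict), stringsAsFactors = FALSE)
  class(out) <- c("branch_support", "data.frame")
  out
}

#' Greedy best-path placement on the tree
#'
#' Descends from the root, at each node taking the child branch with maximal
#' net score (support - conflict) and accepting it only when support >= 1
#' and net > 0; stops at ties (reported), at a leaf, or when no child is
#' acceptable.
#'
#' @param tree the rooted `ape::phylo` the support table refers to.
#' @param table a `branch_support` data.frame for one read set.
#' @return a `placement_result`: list with `path` (branch ids from the
#'   root), `scores` (per-branch support/conflict/net along with all
#'   branches), `terminal_branch`, `stop_reason` (`"leaf"`, `"tie"`,
#'   `"no_signal"`, `"no_acceptable_child"`).
#' @export
best_path <- function(tree, table) {
  bt <- .branch_table(tree)
  sup <- setNames(table$support, table$branch_id)[bt$branch_id]
  con <- setNames(table$conflict, table$branch_id)[bt$branch_id]
  net <- sup - con
  nt <- length(tree$tip.label)
  cur <- nt + 1L                              # root
  path <- character(0)
  reason <- NULL
  repeat {
    kids <- which(bt$parent_node == cur)
    if (!length(kids)) { reason <- "leaf"; break }
    m <- max(net[kids])
    if (!is.finite(m) || m <= 0) {
      reason <- if (length(path)) "no_acceptable_child" else "no_signal"
      break
    }
    cand <- kids[net[kids] == m]
    if (length(cand) > 1) { reason <- "tie"; break }
    path <- c(path, bt$branch_id[cand])
    cur <- bt$child_node[cand]
  }
  scores <- data.frame(branch_id = bt$branch_id, support = unname(sup),
                       conflict = unname(con), net = unname(net),
                       stringsAsFactors = FALSE)
  structure(list(path = path,
                 terminal_branch = if (length(path)) tail(path, 1) else NA_character_,
                 scores = scores, stop_reason = reason),
            class = "placement_result")
}

#' @export
print.placement_result <- function(x, ...) {
  cat(sprintf("placement: %s (stop: %s)\n",
              if (length(x$path)) paste(x$path, collapse = " -> ") else "<empty>",
              x$stop_reason))
  invisible(x)
}

#' Dual-path report for a competitively partitioned mixture
#'
#' Runs the tally and best-path placement for the three read sets of a
#' competitive partition and checks whether the shared set's support is
#' confined to branches common to both unique sets' root paths (the
#' expected picture when two species contribute to one sample).
#'
#' @param aln_sets named list of `alignments` on consensus coordinates, with
#'   elements `unique_a`, `unique_b`, `shared`.
#' @param map a `branch_variant_map`.
#' @param sites the `biallelic_sites` used to build the map.
#' @param consensus_length consensus sequence length.
#' @param transversions_only restrict to transversion sites.
#' @return list with `placements` (per set), `support` (per set),
#'   `common_branches`, `shared_confined` (logical: shared support only on
#'   common branches), and `combined` (wide per-branch table).
#' @export
dual_path_report <- function(aln_sets, map, sites, consensus_length,
                             transversions_only = TRUE) {
  stopifnot(all(c("unique_a", "unique_b", "shared") %in% names(aln_sets)))
  tallies <- lapply(aln_sets, tally_branch_support, map = map, sites = sites,
                    consensus_length = consensus_length,
                    transversions_only = transversions_only)
  placements <- lapply(tallies, best_path, tree = map$tree)
  common <- intersect(placements$unique_a$path, placements$unique_b$path)
  shared_supported <- tallies$shared$branch_id[tallies$shared$support > 0]
  combined <- tallies$unique_a[, "branch_id", drop = FALSE]
  for (s in names(tallies)) {
    combined[[paste0(s, "_support")]] <- tallies[[s]]$support
    combined[[paste0(s, "_conflict")]] <- tallies[[s]]$conflict
  }
  list(placements = placements, support = tallies,
       common_branches = common,
       shared_confined = all(shared_supported %in% common),
       combined = combined)
}
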