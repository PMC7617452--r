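test_that("biallelic site extraction applies the reference and class filters", {
  msa <- c(R = "ACGTAC", X = "ACCTAC", Y = "CCCTAT", Z = "-CCAAT")
  # col1 A,A,C,-: ref A ok, scored {R,X,Y}, alleles {A,C} transversion
  # col2 C,C,C,C: monomorphic -> dropped
  # col3 G,C,C,C: alleles {C,G} transversion
  # col4 T,T,T,A: alleles {A,T} transversion
  # col5 A,A,A,A: monomorphic
  # col6 C,C,T,T: transition C/T
  sites <- extract_biallelic_sites(msa, transversions_only = FALSE,
                                   reference_row = "R")
  expect_identical(sites$col0, c(0L, 2L, 3L, 5L))
  expect_identical(sites$carriers1[[1]], c("R", "X"))     # allele A
  expect_identical(sites$carriers2[[1]], "Y")             # allele C, Z unscored
  tv <- extract_biallelic_sites(msa, transversions_only = TRUE,
                                 reference_row = "R")
  expect_identical(tv$col0, c(0L, 2L, 3L))                # C/T column dropped

  # '-' in the reference row drops the column
  msa2 <- c(R = "-CA", X = "ACA", Y = "TCC")
  s2 <- extract_biallelic_sites(msa2, reference_row = "R")
  expect_identical(s2$col0, 2L)

  expect_error(extract_biallelic_sites(msa, reference_row = "missing"), "absent")
})

test_that("MSA consensus follows plurality with fixed tie order", {
  msa <- c(a = "AA-A", b = "AC-A", c = "AC-C", d = "CA-C")
  # col1 plurality A; col2 tie A/C -> A; col3 all gaps -> N; col4 tie -> A
  expect_identical(consensus_from_msa(msa), "AANA")
  expect_identical(consensus_from_msa(c(x = "A", y = "A", z = "C")), "A")
  # gap plurality -> N
  expect_identical(consensus_from_msa(c(x = "-", y = "-", z = "A", w = "-")), "N")
})

test_that("pileup consensus reproduces the 66%/3x truth table", {
  cases <- list(
    list(counts = c(A = 2L, C = 0L, G = 0L, T = 0L), out = "N"),  # depth 2 < 3
    list(counts = c(A = 7L, C = 3L, G = 0L, T = 0L), out = "A"),  # 0.70 >= 0.66
    list(counts = c(A = 6L, C = 4L, G = 0L, T = 0L), out = "N"),  # 0.60 < 0.66
    list(counts = c(A = 2L, C = 1L, G = 0L, T = 0L), out = "A"),  # 2/3 >= 0.66? 0.667
    list(counts = c(A = 0L, C = 0L, G = 3L, T = 0L), out = "G"),
    list(counts = c(A = 0L, C = 0L, G = 0L, T = 0L), out = "N"))
  pile <- do.call(rbind, lapply(cases, `[[`, "counts"))
  expect_identical(consensus_from_pileup(pile),
                   paste(vapply(cases, `[[`, "", "out"), collapse = ""))

  # monotonicity: raising thresholds never converts N to a base
  withr::with_seed(131, {
    pile2 <- matrix(rpois(200, 2), ncol = 4, dimnames = list(NULL, c("A","C","G","T")))
    base <- strsplit(consensus_from_pileup(pile2, 0.66, 3), "")[[1]]
    for (mf in c(0.75, 0.9)) for (md in c(4, 6)) {
      harder <- strsplit(consensus_from_pileup(pile2, mf, md), "")[[1]]
      expect_true(all(harder[base == "N"] == "N"))
    }
  })
})

test_that("site-to-branch assignment matches clades and polarity", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  mk_site <- function(c1, c2, a1 = "A", a2 = "T") {
    s <- data.frame(col0 = 0L, allele1 = a1, allele2 = a2,
                    is_transversion = TRUE)
    s$carriers1 <- list(c1); s$carriers2 <- list(c2)
    class(s) <- c("biallelic_sites", "data.frame")
    s
  }
  # allele T carried by {A,B}, outgroup D -> stem branch of (A,B), derived T
  m1 <- assign_sites_to_branches(tree, mk_site(c("C", "D"), c("A", "B")), "D")
  expect_identical(m1$assignments$derived, "T")
  leaves <- m1$branches$leaves[[match(m1$assignments$branch_id,
                                      m1$branches$branch_id)]]
  expect_identical(leaves, c("A", "B"))

  # {A,C} matches no clade -> homoplasic
  m2 <- assign_sites_to_branches(tree, mk_site(c("A", "C"), c("B", "D")), "D")
  expect_identical(nrow(m2$assignments), 0L)
  expect_identical(m2$unassigned$reason, "homoplasic")

  # singleton allele in A -> terminal branch of A
  m3 <- assign_sites_to_branches(tree, mk_site("A", c("B", "C", "D")), "D")
  expect_identical(m3$assignments$branch_id, "A")
  expect_identical(m3$assignments$derived, "A")  # allele1 carried by A only

  # unscored outgroup at a root split -> polarity undetermined, missing_data
  m4 <- assign_sites_to_branches(tree, mk_site(c("A", "B"), "C"), "D")
  expect_identical(m4$unassigned$reason, "missing_data")

  expect_error(assign_sites_to_branches(tree, mk_site("Q", "A"), "D"), "missing")
})

test_that("assignment is invariant to MSA row order", {
  tree <- toy_tree()
  sim <- simulate_tree_msa(tree, 600, 6, seed = 141)
  s1 <- extract_biallelic_sites(sim$msa, TRUE, reference_row = "A")
  s2 <- extract_biallelic_sites(sim$msa[rev(seq_along(sim$msa))], TRUE,
                                reference_row = "A")
  m1 <- assign_sites_to_branches(tree, s1, "O")
  m2 <- assign_sites_to_branches(tree, s2, "O")
  expect_identical(m1$assignments, m2$assignments)
  # every assigned site appears under exactly one branch
  expect_identical(anyDuplicated(m1$assignments$site), 0L)

  # infinite-sites simulation: branch site sets are recovered exactly for
  # internal branches and tips (modulo the root-edge polarity pair)
  for (b in c("A", "B", "C", "D", "E")) {
    got <- sort(m1$assignments$col0[m1$assignments$branch_id == b])
    expect_identical(got, sim$branch_sites[[b]])
  }
})

test_that("branch tally counts support and conflict by construction", {
  tree <- toy_tree()
  sim <- simulate_tree_msa(tree, 2000, 8, seed = 151)
  sites <- extract_biallelic_sites(sim$msa, TRUE, reference_row = "A")
  map <- assign_sites_to_branches(tree, sites, "O")
  cons <- consensus_from_msa(sim$msa)

  # error-free reads from leaf B covering everything
  rd <- simulate_ancient_reads(sim$msa[["B"]], 400, fragment_model(),
                               damage_model(0, 0, 0), 0, seed = 152)
  aln <- map_reads_end_to_end(rd, c(cons = cons), max_mismatch_rate = 0.2)
  tab <- tally_branch_support(aln, map, sites, nchar(cons))

  bt <- map$branches
  root_path <- c()  # branches from root to B
  cur <- "B"
  repeat {
    row <- match(cur, bt$branch_id)
    root_path <- c(root_path, cur)
    parent <- bt$parent_node[row]
    nxt <- which(bt$child_node == parent)
    if (!length(nxt)) break
    cur <- bt$branch_id[nxt]
  }
  per_branch <- table(map$assignments$branch_id)
  for (i in seq_len(nrow(tab))) {
    b <- tab$branch_id[i]
    n_sites_b <- if (b %in% names(per_branch)) as.integer(per_branch[[b]]) else 0L
    covered <- tab$support[i] + tab$conflict[i]
    expect_lte(covered, n_sites_b)
    if (b %in% root_path) expect_identical(tab$conflict[i], 0L)
    else expect_identical(tab$support[i], 0L)
  }

  # no reads: all-zero table
  tab0 <- tally_branch_support(aln[0, ], map, sites, nchar(cons))
  expect_identical(sum(tab0$support) + sum(tab0$conflict), 0L)

  # a single read carrying the ancestral allele at one branch site
  asg <- map$assignments[map$assignments$branch_id == "C", ][1, ]
  anc_read <- substr(cons, asg$col0 - 10, asg$col0 + 30)
  substr(anc_read, 12, 12) <- asg$ancestral
  aln1 <- data.frame(read_id = "anc", ref_id = "cons", start = asg$col0 - 11L,
                     strand = "+", aligned_length = nchar(anc_read),
                     edit_distance = 1L, score = 1, map_score = 37L,
                     seq = anc_read, stringsAsFactors = FALSE)
  t1 <- tally_branch_support(aln1, map, sites, nchar(cons))
  expect_identical(t1$conflict[t1$branch_id == "C"], 1L)

  # coordinates beyond the consensus are an error
  bad <- aln1; bad$start <- nchar(cons) - 5L
  expect_error(tally_branch_support(bad, map, sites, nchar(cons)), "exceed")
})

test_that("best path follows net score and stops at ties", {
  tree <- toy_tree()
  bt <- sedna:::.branch_table(tree)
  zero <- data.frame(branch_id = bt$branch_id, support = 0L, conflict = 0L)

  # all-zero: empty path, "no signal"
  p0 <- best_path(tree, zero)
  expect_length(p0$path, 0)
  expect_identical(p0$stop_reason, "no_signal")

  # support along root -> C only
  tab <- zero
  cpath <- c("n8", "n10", "C")   # clade(ABCD), clade(CD), C for this toy tree
  tab$support[tab$branch_id %in% cpath] <- 5L
  p1 <- best_path(tree, tab)
  expect_identical(p1$path, cpath)
  expect_identical(p1$terminal_branch, "C")
  expect_identical(p1$stop_reason, "leaf")

  # two children at net +3: stop at the parent with reason "tie"
  tab2 <- zero
  tab2$support[tab2$branch_id == "n8"] <- 4L
  tab2$support[tab2$branch_id %in% c("n9", "n10")] <- 3L
  p2 <- best_path(tree, tab2)
  expect_identical(p2$path, "n8")
  expect_identical(p2$stop_reason, "tie")

  # net <= 0 is not acceptable even with support
  tab3 <- zero
  tab3$support[tab3$branch_id == "n8"] <- 2L
  tab3$conflict[tab3$branch_id == "n8"] <- 2L
  p3 <- best_path(tree, tab3)
  expect_identical(p3$stop_reason, "no_signal")
})
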