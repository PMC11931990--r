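two_residue_model <- function(sep) {
  atoms_model(data.frame(
    chain = c("A", "C"), resno = c(10, 20), resid = c("ARG", "ASP"),
    elety = "CB", x = c(0, sep), y = 0, z = 0))
}

test_that("contact detection respects the distance cutoff", {
  hit <- find_contacts(two_residue_model(2.5), cutoff = 3.0)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$min_distance, 2.5)
  expect_equal(hit$agp1_resno, 10)
  expect_equal(hit$agp2_resno, 20)
  expect_equal(nrow(find_contacts(two_residue_model(3.5), cutoff = 3.0)), 0)
  expect_error(find_contacts(two_residue_model(2), chain_map =
                               list(agp1 = character(), agp2 = "C")),
               "at least one chain")
})

test_that("contacts match a brute-force all-atom-pairs oracle", {
  brute_contacts <- function(model, cutoff) {
    at <- model$atoms
    a1 <- at[at$chain %in% c("A", "B"), ]
    a2 <- at[at$chain %in% c("C", "D"), ]
    out <- list()
    for (i in unique(paste(a1$chain, a1$resno))) {
      p <- a1[paste(a1$chain, a1$resno) == i, ]
      for (j in unique(paste(a2$chain, a2$resno))) {
        q <- a2[paste(a2$chain, a2$resno) == j, ]
        dm <- Inf
        for (r in seq_len(nrow(p))) for (s in seq_len(nrow(q)))
          dm <- min(dm, sqrt(sum((unlist(p[r, c("x", "y", "z")]) -
                                  unlist(q[s, c("x", "y", "z")]))^2)))
        if (dm <= cutoff)
          out[[length(out) + 1L]] <- data.frame(
            key = paste(i, j), min_distance = dm)
      }
    }
    if (length(out)) do.call(rbind, out) else
      data.frame(key = character(), min_distance = numeric())
  }
  for (seed in c(3, 11, 27)) {
    sc <- synthetic_complex(seed = seed, side_chains = TRUE)
    got <- find_contacts(sc$model, cutoff = 6)
    want <- brute_contacts(sc$model, 6)
    expect_equal(nrow(got), nrow(want))
    got_key <- paste(got$agp1_chain, got$agp1_resno, got$agp2_chain,
                     got$agp2_resno)
    expect_setequal(got_key, want$key)
    want_sorted <- want[match(got_key, want$key), ]
    expect_equal(got$min_distance, want_sorted$min_distance, tolerance = 1e-9)
  }
})

test_that("growing the cutoff never removes contact pairs", {
  sc <- synthetic_complex(seed = 13, side_chains = TRUE)
  prev <- character(0)
  for (cutoff in c(3, 4.5, 6, 8)) {
    ct <- find_contacts(sc$model, cutoff = cutoff)
    keys <- paste(ct$agp1_chain, ct$agp1_resno, ct$agp2_chain, ct$agp2_resno)
    expect_true(all(prev %in% keys))
    prev <- keys
  }
})

test_that("swapping the chain map transposes pairs, preserving distances", {
  sc <- synthetic_complex(seed = 13, side_chains = TRUE)
  fwd <- find_contacts(sc$model, cutoff = 6)
  rev <- find_contacts(sc$model, chain_map = list(agp2 = c("C", "D"),
                                                  agp1 = c("A", "B")),
                       cutoff = 6)
  expect_equal(sort(fwd$min_distance), sort(rev$min_distance))
  expect_setequal(paste(fwd$agp1_resno, fwd$agp2_resno),
                  paste(rev$agp1_resno, rev$agp2_resno))
})

test_that("interface residues group into regions split by gaps and chains", {
  mk <- function(resno, chain) data.frame(
    agp1_resid = "ALA", agp1_resno = resno, agp1_chain = chain,
    agp2_resid = "GLY", agp2_resno = 1, agp2_chain = "C",
    min_distance = 2)
  # 524-549 holds together across 11- and 14-residue gaps at threshold 15
  g <- group_contacts(rbind(mk(524, "B"), mk(535, "B"), mk(549, "B")))
  expect_equal(nrow(g$groups), 1)
  expect_equal(g$groups$first, 524)
  expect_equal(g$groups$last, 549)
  expect_equal(nrow(g$solo), 0)
  # a residue on the other chain never merges in
  g2 <- group_contacts(rbind(mk(549, "B"), mk(554, "A")))
  expect_equal(nrow(g2$groups), 0)
  expect_equal(nrow(g2$solo), 2)
  # a single residue is a solo residue
  g3 <- group_contacts(mk(524, "B"))
  expect_equal(nrow(g3$groups), 0)
  expect_equal(g3$solo$resno, 524)
  # threshold 0 keeps only consecutive runs together
  g4 <- group_contacts(rbind(mk(10, "A"), mk(11, "A"), mk(13, "A")),
                       gap_threshold = 0)
  expect_equal(g4$groups$first, 10)
  expect_equal(g4$groups$last, 11)
  expect_equal(g4$solo$resno, 13)
  # threshold at least the largest gap yields one group per chain
  g5 <- group_contacts(rbind(mk(10, "A"), mk(80, "A"), mk(12, "B")),
                       gap_threshold = 70)
  expect_equal(nrow(g5$groups), 1)
  expect_equal(nrow(g5$solo), 1)
})

test_that("grouping a published-model interface keeps regions on their chains", {
  # residue/chain pattern of one selected pose's interface on the acceptor
  # protein: helix 524-549 on chain B, the ATPase patches, and the solo
  # substrate-adjacent Lys554 on chain A
  resno <- c(524, 531, 531, 531, 535, 535, 535, 539, 542, 542, 542, 545,
             546, 546, 547, 549, 549, 554, 574, 578, 603, 604, 604, 604,
             607, 607, 613, 632, 633, 636, 647, 648, 648, 648, 648, 649,
             649, 649, 650, 652, 673, 679, 671, 684, 684, 686, 686, 687,
             687, 717)
  chain <- ifelse(resno >= 613 | resno == 554, "A", "B")
  chain[resno %in% c(632, 633, 636)] <- "B"
  ct <- data.frame(agp1_resid = "X", agp1_resno = resno, agp1_chain = chain,
                   agp2_resid = "Y", agp2_resno = 1, agp2_chain = "C",
                   min_distance = 2)
  g <- group_contacts(ct)
  # the 524-549 helix is one region on chain B
  helix <- g$groups[g$groups$first == 524, ]
  expect_equal(helix$chain, "B")
  expect_equal(helix$last, 549)
  # Lys554 stays solo on chain A despite the chain-B 549 within 5 residues
  expect_true(any(g$solo$chain == "A" & g$solo$resno == 554))
  # no group spans both chains
  for (i in seq_len(nrow(g$groups))) {
    members <- as.integer(strsplit(g$groups$residues[i], ",")[[1]])
    expect_true(all(ct$agp1_chain[match(members, ct$agp1_resno)] ==
                    g$groups$chain[i]))
  }
})

test_that("conservation lookup maps reference positions through gaps", {
  msa <- c(ref = "AR-G", query = "ARCG")
  got <- conservation_column(msa, "ref", 3)
  expect_equal(attr(got, "column"), 4)
  expect_equal(unname(got["query"]), "G")
  expect_equal(unname(got["ref"]), "G")
  # identical ungapped sequences agree at every position
  msa2 <- c(a = "MKLVR", b = "MKLVR")
  expect_equal(as.character(conservation_column(msa2, "a", 5)), c("R", "R"))
  expect_error(conservation_column(msa, "ref", 0), "positive")
  expect_error(conservation_column(msa, "ref", 4), "ungapped length")
  expect_error(conservation_column(msa, "nope", 1), "not in the alignment")
  expect_error(conservation_column(c(a = "AB", b = "ABC"), "a", 1),
               "same length")
})
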