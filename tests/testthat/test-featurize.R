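test_that("windowed composition matches a brute-force counting oracle", {
  # homopolymer: Ala frequency 1, everything else 0
  fa <- composition_features(strrep("A", 30))
  expect_true(all(fa[, "comp_A_w11"] == 1))
  expect_true(all(fa[, "comp_C_w11"] == 0))
  # terminal truncation: first residue of a window-11 column averages 6 cells
  s <- "ACDEFGHIKLMNPQRSTVWY"
  chars <- strsplit(s, "")[[1]]
  f <- composition_features(s)
  expect_equal(unname(f[1, "comp_A_w11"]), sum(chars[1:6] == "A") / 6)
  expect_equal(unname(f[1, "comp_C_w11"]), 1 / 6)
  # random 50-mer against the per-position loop oracle, all letters/windows
  withr::with_seed(5, seq50 <- random_sequence(50))
  ch <- strsplit(seq50, "")[[1]]
  f50 <- composition_features(seq50)
  for (w in c(5, 11, 21)) {
    for (a in c("A", "G", "W")) {
      oracle <- window_mean_oracle(as.numeric(ch == a), w)
      expect_equal(unname(f50[, sprintf("comp_%s_w%d", a, w)]), oracle)
    }
  }
  # X is excluded from numerator and denominator
  fx <- composition_features("AXA")
  expect_equal(unname(fx[, "comp_A_w5"]), c(1, 1, 1))
})

test_that("windowed entropy, charge and scale averages follow the definitions", {
  f <- physchem_features(strrep("A", 25))
  expect_true(all(f[, "entropy_w11"] == 0))
  # equal halves of two residue types give exactly 1 bit mid-window
  f2 <- physchem_features("AAAAACCCCC")
  expect_equal(unname(f2[5, "entropy_w11"]), 1)  # truncated window holds 5 A + 5 C
  # charge runs: KKKDDD has a 3-run of + at the start, 3-run of - at the end
  f3 <- physchem_features("KKKDDD")
  expect_equal(unname(f3[, "pos_charge_run"]), c(3, 3, 3, 0, 0, 0))
  expect_equal(unname(f3[, "neg_charge_run"]), c(0, 0, 0, 3, 3, 3))
  # windowed Kyte-Doolittle average against the sliding-mean oracle
  withr::with_seed(6, s <- random_sequence(60))
  ch <- strsplit(s, "")[[1]]
  f60 <- physchem_features(s)
  kd <- unname(chezodr:::KYTE_DOOLITTLE[ch])
  expect_equal(unname(f60[, "hydropathy_kd_w11"]),
               window_mean_oracle(kd, 11))
})

test_that("structure propensities and hydrophobic clusters behave as defined", {
  # homopolymer: all structure columns constant along the interior
  fs <- structure_features(strrep("L", 40))
  interior <- 11:30
  for (col in colnames(fs)) {
    expect_lt(diff(range(fs[interior, col])), 1e-12)
  }
  # poly-I: a single cluster spanning the sequence
  fi <- structure_features(strrep("I", 15))
  expect_true(all(fi[, "hydrophobic_cluster_len"] == 15))
  expect_true(all(fi[, "hydrophobic_cluster_dist"] == 0))
  # windowed Chou-Fasman helix propensity equals the sliding-mean oracle
  withr::with_seed(7, s <- random_sequence(60))
  ch <- strsplit(s, "")[[1]]
  f60 <- structure_features(s)
  cf <- unname(chezodr:::CHOU_FASMAN_HELIX[ch])
  expect_equal(unname(f60[, "cf_helix_w21"]), window_mean_oracle(cf, 21))
  # isolated hydrophobics are not clusters; distance counts to the nearest one
  fm <- structure_features("ILAAAAAAGG")
  expect_equal(unname(fm[, "hydrophobic_cluster_len"]),
               c(2, 2, rep(0, 8)))
  expect_equal(unname(fm[, "hydrophobic_cluster_dist"]),
               c(0, 0, 1, 2, 3, 4, 5, 6, 7, 8))
})

test_that("pattern features flag tandem repeats, motifs and low complexity", {
  fp <- pattern_features("HEHEHEHE")
  expect_true(all(fp[, "tandem_repeat"] == 1))
  expect_true(all(fp[, "tandem_repeat_copies"] == 4))
  expect_true(all(fp[, "low_complexity"] == 1))
  # a high-complexity non-repetitive sequence has empty repeat columns
  fr <- pattern_features("ACDEFGHIKLMNPQRSTVWY")
  expect_true(all(fr[, "tandem_repeat"] == 0))
  expect_true(all(fr[, "low_complexity"] == 0))
  # planted SH3-type motif PxxP: independent regex scan oracle
  s <- "AAAAAPKLPAAAAA"
  fmot <- pattern_features(s)
  hit <- regexpr("P..P", s)
  span <- hit:(hit + attr(hit, "match.length") - 1)
  oracle <- as.numeric(seq_len(nchar(s)) %in% span)
  expect_equal(unname(fmot[, "slim_motif_count"]), oracle)
})

test_that("evolutionary profile features match hand counts on a toy MSA", {
  entry <- protein_entry("q", "ACD")
  # single-sequence MSA: one-hot profile, entropy 0, gap fraction 0
  m1 <- msa_from_strings("ACD")
  f1 <- evo_features(entry, m1)
  expect_equal(unname(f1[, "profile_A"]), c(1, 0, 0))
  expect_equal(unname(f1[, "profile_entropy"]), c(0, 0, 0))
  expect_equal(unname(f1[, "gap_fraction"]), c(0, 0, 0))
  expect_equal(unname(f1[, "query_agreement"]), c(1, 1, 1))
  expect_equal(ncol(f1), 27L)
  # 3-row toy: hand-tallied frequencies and gap fractions
  m3 <- msa_from_strings(c("ACD", "ACE", "-CD"))
  f3 <- evo_features(entry, m3)
  expect_equal(unname(f3[, "profile_A"]), c(1, 0, 0))      # A,A of 2 non-gap
  expect_equal(unname(f3[, "profile_C"]), c(0, 1, 0))
  expect_equal(unname(f3[, "profile_D"]), c(0, 0, 2 / 3))
  expect_equal(unname(f3[, "profile_E"]), c(0, 0, 1 / 3))
  expect_equal(unname(f3[, "gap_fraction"]), c(1 / 3, 0, 0))
  expect_equal(unname(f3[, "n_eff"]), c(3, 3, 3))
  # column of all gaps in non-query rows
  mg <- msa_from_strings(c("ACD", "A-D", "A-D"))
  fg <- evo_features(entry, mg)
  expect_equal(unname(fg[2, "gap_fraction"]), 2 / 3)
  # query mismatch is an error
  expect_error(evo_features(protein_entry("q", "ACC"), m3), "does not match")
})

test_that("feature matrix has the frozen manifest order and column counts", {
  entry <- protein_entry("p", "MKVLAAGGSPQRSTKKEEDDAAGG")
  fm <- build_feature_matrix(entry)
  expect_s3_class(fm, "feature_matrix")
  expect_equal(ncol(fm$values), 130L)
  msa <- mutate_msa(entry, n_rows = 4L, seed = 2L)
  fme <- build_feature_matrix(entry, msa = msa)
  expect_equal(ncol(fme$values), 157L)
  # golden manifest: names and groups match the versioned file
  golden <- read.delim(system.file("extdata", "feature_manifest_v1.tsv",
                                   package = "chezodr"))
  expect_equal(fme$names, golden$name)
  expect_equal(fme$group, golden$group)
  expect_equal(feature_manifest(evolution = FALSE)$name, golden$name[1:130])
  # determinism
  fm2 <- build_feature_matrix(entry)
  expect_identical(fm$values, fm2$values)
})

test_that("all features are finite for arbitrary sequences and symmetric windows reverse", {
  withr::with_seed(9, {
    for (L in c(1, 2, 5, 21, 200, 1500)) {
      s <- random_sequence(L, letters = c(chezodr::AA_ALPHABET, "X"))
      fm <- build_feature_matrix(protein_entry("r", s))
      expect_true(all(is.finite(fm$values)), info = paste("L =", L))
    }
    # reversal equivariance of symmetric window features
    s <- random_sequence(80)
    rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    f_fwd <- build_feature_matrix(protein_entry("f", s))$values
    f_rev <- build_feature_matrix(protein_entry("b", rev_s))$values
    for (col in c("comp_A_w11", "entropy_w11", "hydropathy_kd_w21",
                  "cf_sheet_w5", "net_charge_w5")) {
      expect_equal(unname(f_fwd[, col]), rev(unname(f_rev[, col])),
                   info = col)
    }
  })
})

test_that("normalization standardizes training residues and zeroes constant columns", {
  withr::with_seed(10, {
    mats <- lapply(1:3, function(i) {
      build_feature_matrix(protein_entry(paste0("n", i),
                                         random_sequence(60)))
    })
  })
  norm <- fit_normalizer(mats)
  pool <- do.call(rbind, lapply(mats, function(m) {
    apply_normalizer(m, norm)
  }))
  live <- !norm$constant
  expect_lt(max(abs(colMeans(pool[, live]))), 1e-9)
  expect_lt(max(abs(apply(pool[, live], 2, sd) - 1)), 1e-9)
  expect_true(all(pool[, norm$constant] == 0))
  # held-out matrix equals the elementwise (x - m) / s oracle
  withr::with_seed(11, held <- build_feature_matrix(
    protein_entry("h", random_sequence(40))))
  got <- apply_normalizer(held, norm)
  manual <- sweep(sweep(held$values, 2, norm$mean), 2,
                  ifelse(norm$constant, 1, norm$sd), "/")
  manual[, norm$constant] <- 0
  expect_equal(got, manual)
  expect_error(fit_normalizer(list()))
})
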