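test_that("dimension arithmetic follows the closed form on known configurations", {
  cases <- list(
    list(c("no_reduction", "hydro"), c("counts", "tfeat"), c(1, 3), 45L),
    list(c("conform", "no_reduction", "hydro"), c("counts", "mat"), c(1, 3), 980L),
    list(c("conform", "no_reduction"), "mat", c(1, 3), 898L),
    list("no_reduction", c("counts", "mat"), c(1, 2), 820L),
    list("hydro", "tfeat", 1:3, 15L))
  for (cs in cases) {
    spec <- feature_spec(cs[[1]], cs[[2]], cs[[3]])
    expect_identical(feature_dimension(spec), cs[[4]])
    expect_length(feature_names(spec), cs[[4]])
  }
  expect_identical(
    feature_dimension(feature_spec("no_reduction", character(0), 1)), 0L)
})

test_that("embedding blocks contribute their per-representation dimension", {
  spec <- feature_spec(c("no_reduction", "hydro"), c("tfeat", "pro2vec"), 3)
  expect_identical(feature_dimension(spec), 360L)  # 2*5 + 50 + 300
  custom <- feature_spec("hydro", "pro2vec", 1,
                         embedding_config = list(hydro = list(dimension = 32)))
  expect_identical(feature_dimension(custom), 32L)
  nm <- feature_names(custom)
  expect_identical(nm[1], "hydro:p2v_1")
  expect_identical(nm[32], "hydro:p2v_32")
})

test_that("feature names are canonical, unique and aligned with the vector", {
  spec <- feature_spec(c("no_reduction", "hydro"), c("counts", "mat", "tfeat"),
                       c(1, 3))
  nm <- feature_names(spec)
  expect_false(anyDuplicated(nm) > 0)
  expect_identical(nm[1:20], load_alphabet("no_reduction")$symbols)
  expect_true("K" %in% nm)
  expect_true("H_2H_2(1)" %in% nm)
  expect_true("H_2H_2(3)" %in% nm)
  expect_true("hydro:energy(1)" %in% nm)
  # representation-major, counts -> mat -> tfeat order
  expect_lt(match("K", nm), match("AA(1)", nm))
  expect_lt(match("AA(1)", nm), match("no_reduction:energy(1)", nm))
  expect_lt(match("no_reduction:entropy(3)", nm), match("H_1", nm))
  # the extracted vector carries exactly these names in this order
  v <- extract_features("ACDKYTRWSACDKYTRWSACDKYTRWSACDK", spec)
  expect_identical(names(v), nm)
})

test_that("spec validation rejects malformed configurations", {
  expect_error(feature_spec(c("hydro", "hydro"), "counts", 1), "duplicate")
  expect_error(feature_spec("hydro", c("counts", "counts"), 1), "duplicate")
  expect_error(feature_spec("hydro", "dipeptide", 1), "unknown feature type")
  expect_error(feature_spec("hydro", "counts", c(1, 1)), "duplicate")
  expect_error(feature_spec("hydro", "counts", 0), "positive")
  expect_error(feature_spec("martian", "counts", 1), "unknown alphabet")
})

test_that("extracted vectors equal the concatenation of independent blocks", {
  set.seed(51)
  s <- random_aa_seq(31)
  spec <- feature_spec(c("conform", "no_reduction"), c("counts", "mat", "tfeat"),
                       c(1, 2))
  v <- extract_features(s, spec)
  expect_length(v, feature_dimension(spec))
  # block-wise oracle computed through the layer functions directly
  want <- numeric(0)
  for (name in c("conform", "no_reduction")) {
    rs <- reduce_sequence(s, name)
    want <- c(want, monogram_counts(rs))
    for (d in 1:2) want <- c(want, bigram_vector(cooccurrence_matrix(rs, d)))
    for (d in 1:2) {
      tf <- texture_features(cooccurrence_matrix(rs, d))
      names(tf) <- paste0(name, ":", names(tf), "(", d, ")")
      want <- c(want, tf)
    }
  }
  expect_equal(v, want)
  # purity: repeated extraction is identical
  expect_identical(v, extract_features(s, spec))
})

test_that("normalized blocks each sum to one per sequence", {
  set.seed(52)
  spec <- feature_spec(c("conform", "no_reduction", "hydro"),
                       c("counts", "mat"), c(1, 3))
  expect_identical(feature_dimension(spec), 980L)
  v <- extract_features(random_aa_seq(31), spec)
  nm <- names(v)
  for (rep_k in list(c("conform", 7), c("no_reduction", 20), c("hydro", 5))) {
    syms <- load_alphabet(rep_k[[1]])$symbols
    expect_equal(sum(v[syms]), 1)
    for (d in c(1, 3)) {
      block <- grepl(paste0("\\(", d, "\\)$"), nm) &
        nm %in% as.vector(outer(syms, syms, function(a, b)
          paste0(a, b, "(", d, ")")))
      expect_equal(sum(v[block]), 1)
    }
  }
})

test_that("matrix extraction preserves order, labels and row independence", {
  peps <- generate_synthetic(6, 4, seed = 53)
  spec <- feature_spec(c("no_reduction", "hydro"), c("counts", "tfeat"), c(1, 3))
  fm <- extract_matrix(peps, spec)
  expect_identical(dim(fm$x), c(10L, 45L))
  expect_identical(rownames(fm$x), peps$id)
  expect_identical(fm$labels, peps$label)
  # shuffled dataset gives the same rows, reordered
  set.seed(54)
  ord <- sample(nrow(peps))
  fm2 <- extract_matrix(peps[ord, ], spec)
  expect_equal(fm2$x, fm$x[ord, ])
  # the "K" column equals a per-sequence lysine tally
  spec_counts <- feature_spec("no_reduction", "counts", 1)
  fmc <- extract_matrix(peps, spec_counts)
  k_frac <- vapply(peps$sequence, function(s)
    sum(strsplit(s, "")[[1]] == "K") / nchar(s), numeric(1), USE.NAMES = FALSE)
  expect_equal(unname(fmc$x[, "K"]), k_frac)
})

test_that("pro2vec extraction requires a model and reports the culprit id", {
  spec <- feature_spec("hydro", "pro2vec", 1)
  expect_error(extract_features("ACDEFGHIKL", spec), "no embedding model")
  peps <- generate_synthetic(2, 2, seed = 55)
  peps$sequence[2] <- "ACDEFXGHIKL"
  spec2 <- feature_spec("no_reduction", "counts", 1)
  expect_error(extract_matrix(peps, spec2), peps$id[2])
})

test_that("feature CSV export carries names, ids and labels", {
  peps <- generate_synthetic(3, 2, seed = 56)
  spec <- feature_spec("hydro", c("counts", "mat"), 1)
  fm <- extract_matrix(peps, spec)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(fm, path)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_identical(names(back), c("id", feature_names(spec), "label"))
  expect_equal(as.matrix(back[, feature_names(spec)]), fm$x,
               ignore_attr = TRUE)
  expect_identical(back$label, peps$label)
})
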