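mkset <- function(aa, locus = "TRD")
  data.frame(locus = locus, junction_aa = aa, stringsAsFactors = FALSE)

test_that("publicity spans 0 (private) to the full dataset count", {
  sc <- c(lapply(1:6, function(i) mkset(c("CACDTGGYWDTRQMFF", "CAFPRIVATE"[i == 1]))),
          lapply(1:3, function(i) mkset("CACDTGGYWDTRQMFF")))
  names(sc) <- c(sprintf("FT%d", 1:6), sprintf("PNT%d", 1:3))
  bulk <- lapply(1:10, function(i) mkset("CACDTGGYWDTRQMFF"))
  names(bulk) <- sprintf("BULK%d", 1:10)
  pub <- compute_publicity(repertoire_collection(sc, bulk))
  expect_equal(publicity_lookup(pub, "TRD", "CACDTGGYWDTRQMFF"), 19L)
  expect_equal(publicity_lookup(pub, "TRD", "CAFPRIVATE"), 0L)
})

test_that("publicity is 0 iff one dataset, equals the count from two onward", {
  sc <- list(A = mkset(c("CAAA", "CBBB")), B = mkset("CBBB"), C = mkset("CBBB"))
  pub <- compute_publicity(repertoire_collection(sc = sc))
  expect_equal(publicity_lookup(pub, "TRD", "CAAA"), 0L)
  expect_equal(publicity_lookup(pub, "TRD", "CBBB"), 3L)
})

test_that("publicity is monotone under dataset addition and order-invariant", {
  sc <- list(A = mkset("CXXX"), B = mkset(c("CXXX", "CYYY")))
  p1 <- compute_publicity(repertoire_collection(sc = sc))
  p2 <- compute_publicity(repertoire_collection(sc = c(sc, list(C = mkset("CXXX")))))
  expect_gte(publicity_lookup(p2, "TRD", "CXXX"),
             publicity_lookup(p1, "TRD", "CXXX"))
  p3 <- compute_publicity(repertoire_collection(sc = rev(sc)))
  expect_equal(publicity_lookup(p3, "TRD", "CXXX"),
               publicity_lookup(p1, "TRD", "CXXX"))
  # duplicate bulk names merge into one dataset (no double counting)
  blk <- list(S1 = mkset("CZZZ"), S1 = mkset("CZZZ"))
  p4 <- compute_publicity(repertoire_collection(bulk = blk))
  expect_equal(publicity_lookup(p4, "TRD", "CZZZ"), 0L)
})

test_that("Vg9Vd2 classification follows the paired TRGV9/TRDV2 definition", {
  pt <- public_clonotype_table()
  mk <- function(cell, locus, v, i)
    list(cell_id = cell, locus = locus, v_call = v,
         junction_nt = pt$junction_nt[i], junction_aa = pt$junction_aa[i])
  cells <- toy_cells(list(
    mk("vg", "TRD", "TRDV2", 1), mk("vg", "TRG", "TRGV9", 9),
    mk("non", "TRD", "TRDV2", 2), mk("non", "TRG", "TRGV8", 10),
    mk("unp", "TRD", "TRDV2", 3),
    # order-swapped and with an extra non-TRDV2 delta chain
    mk("vg2", "TRG", "TRGV9", 9), mk("vg2", "TRD", "TRDV1", 5),
    mk("vg2", "TRD", "TRDV2", 1)))
  cls <- classify_vg9vd2(cells)
  lab <- stats::setNames(cls$vg9vd2_class, cls$cell_id)
  expect_equal(unname(lab["vg"]), "vg9vd2")
  expect_equal(unname(lab["non"]), "non_vg9vd2")
  expect_equal(unname(lab["unp"]), "unpaired")
  expect_equal(unname(lab["vg2"]), "vg9vd2")
})

test_that("V usage fractions sum to one and pool rare genes as Others", {
  pt <- public_clonotype_table()
  mk <- function(cell, v, i)
    list(cell_id = cell, locus = "TRD", v_call = v,
         junction_nt = pt$junction_nt[i], junction_aa = pt$junction_aa[i])
  cells <- toy_cells(list(mk("a", "TRDV2", 1), mk("b", "TRDV2", 2),
                          mk("c", "TRAV38-2DV8", 3)))
  us <- v_usage(cells, "TRD")
  expect_equal(sum(us$fraction), 1)
  expect_equal(us$fraction[us$gene == "TRDV2"], 2 / 3)
  expect_equal(us$fraction[us$gene == "Others"], 1 / 3)
  cells2 <- toy_cells(list(mk("a", "TRDV2", 1), mk("b", "TRDV2", 2)))
  us2 <- v_usage(cells2, "TRD")
  expect_equal(us2$fraction[us2$gene == "TRDV2"], 1)
})

test_that("simulated V usage is recovered within the binomial 95% CI", {
  cfg <- simulation_config(seed = 41L, public_rate_fetal = 0,
                           public_rate_postnatal = 0,
                           fetal_ages_weeks = c(16, 20),
                           postnatal_ages_years = 4,
                           cells_per_subject = 1200L, bulk_subject_count = 0L)
  sim <- simulate_repertoire(cfg)
  ch <- do.call(rbind, sim$sc[c("FT1", "FT2")])
  trd <- ch[ch$locus == "TRD", ]
  n2 <- sum(trd$v_call == "TRDV2")
  ci <- stats::binom.test(n2, nrow(trd))$conf.int
  expect_true(ci[1] <= 0.74 && 0.74 <= ci[2])
})

test_that("position-5 hydrophobicity reproduces the canonical public patterns", {
  expect_false(position5_hydrophobic("CACDTGGYWDTRQMFF"))    # G neutral
  expect_false(position5_hydrophobic("CACDTGGYSWDTRQMFF"))   # G neutral
  expect_true(position5_hydrophobic("CACDVLGDTDKLIF"))       # L
  expect_true(position5_hydrophobic("CACDILGDTDKLIF"))       # L
  expect_true(position5_hydrophobic("CACDTVLGDTWDTTRQMFF"))  # V
  expect_true(position5_hydrophobic("CACDILGDTWDTTRQMFF"))   # L
  expect_true(position5_hydrophobic("CACDYWGSSWDTRQMFF"))    # W
  expect_false(position5_hydrophobic("CACDWGSSWDTRQMFF"))    # G neutral
  expect_true(is.na(position5_hydrophobic("CACDT")))         # too short
  expect_true(is.na(position5_hydrophobic("AACDTGGYW")))     # no leading C
})

test_that("detection rates are exact on degenerate inputs and error when empty", {
  pt <- public_clonotype_table()
  mk <- function(cell, locus, v, i)
    list(cell_id = cell, locus = locus, v_call = v,
         junction_nt = pt$junction_nt[i], junction_aa = pt$junction_aa[i])
  cells <- toy_cells(list(mk("a", "TRD", "TRDV2", 1), mk("a", "TRG", "TRGV9", 9),
                          mk("b", "TRD", "TRDV2", 2), mk("b", "TRG", "TRGV8", 10)))
  r <- chain_detection_rates(cells)
  expect_equal(c(r$frac_delta, r$frac_gamma, r$frac_double_delta), c(1, 1, 0))
  empty <- structure(list(cells = cells$cells[0, ], chains = cells$chains[0, ]),
                     class = "gdtcr_cells")
  expect_error(chain_detection_rates(empty), "empty")
})

test_that("public tags respect the V gene constraint and flag gamma publics", {
  pt <- public_clonotype_table()
  mk <- function(cell, locus, v, j, i)
    list(cell_id = cell, locus = locus, v_call = v, j_call = j,
         junction_nt = pt$junction_nt[i], junction_aa = pt$junction_aa[i])
  cells <- toy_cells(list(
    mk("t1", "TRD", "TRDV2", "TRDJ3", 2),       # CACDTGGYSWDTRQMFF on TRDV2
    mk("t2", "TRD", "TRDV1", "TRDJ3", 2),       # same aa on TRDV1: not tagged
    mk("g8", "TRG", "TRGV8", "TRGJP1", 10)))    # CATWDTTGWFKIF on TRGV8
  cells <- tag_public_sequences(cells)
  cc <- cells$cells
  expect_true(cc$tag_type1_delta[cc$cell_id == "t1"])
  expect_false(cc$tag_type1_delta[cc$cell_id == "t2"])
  expect_true(cc$tag_public_gamma_v8[cc$cell_id == "g8"])
  bad <- default_public_tags()
  bad$junction_aa[1] <- "CACD1GGY"
  expect_error(tag_public_sequences(cells, bad), "alphabet")
})

test_that("display limits are the 0.2/0.8 quantiles of pooled lengths", {
  lens <- c(39, 42, 42, 45, 45, 48, 48, 51, 54, 57)
  lim <- cdr3_length_display_limits(lens)
  expect_equal(unname(lim["lower"]),
               unname(stats::quantile(lens, 0.2, names = FALSE)))
  expect_equal(unname(lim["upper"]),
               unname(stats::quantile(lens, 0.8, names = FALSE)))
})
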