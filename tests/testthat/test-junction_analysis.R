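g <- synthetic_germline()
v2 <- g[g$name == "TRDV2", ]
j3 <- g[g$name == "TRDJ3", ]
dset <- g[g$segment_type == "D", ]

test_that("a junction concatenating full V and J templates has zero N additions", {
  jx <- paste0(v2$junction_template_nt, j3$junction_template_nt)
  d <- decompose(jx, v2, j3, dset)
  expect_equal(d$n_additions_total, 0L)
  expect_equal(d$v_match_len, nchar(v2$junction_template_nt))
  expect_equal(d$j_match_len, nchar(j3$junction_template_nt))
})

test_that("V trimmed by 2 plus a GGCC insert is scored as 4 N additions with no P", {
  vt <- v2$junction_template_nt
  jx <- paste0(substr(vt, 1, nchar(vt) - 2), "GGCC", j3$junction_template_nt)
  # with no D segments the insert cannot be templated
  d <- decompose(jx, v2, j3, NULL)
  expect_equal(d$n_additions_total, 4L)
  expect_equal(d$p_nt_5v + d$p_nt_3j, 0L)
  expect_equal(d$templated_total, nchar(vt) - 2 + nchar(j3$junction_template_nt))
  # with the full D set, the result must still equal the exhaustive oracle
  o <- oracle_decompose(jx, vt, j3$junction_template_nt,
                        dset$junction_template_nt)
  d2 <- decompose(jx, v2, j3, dset)
  expect_equal(d2$n_additions_total, o$n_additions_total)
  expect_equal(d2$templated_total, o$templated_total)
})

test_that("decomposition equals the exhaustive partition oracle on random junctions", {
  set.seed(91)
  sub <- g[g$name %in% c("TRDV1", "TRDV2", "TRDV3", "TRDD3", "TRDJ1", "TRDJ3"), ]
  dn <- sub$name[sub$segment_type == "D"]
  dsub <- sub[sub$segment_type == "D", ]
  for (i in 1:60) {
    vn <- sample(c("TRDV1", "TRDV2", "TRDV3"), 1)
    jn <- sample(c("TRDJ1", "TRDJ3"), 1)
    jx <- random_junction(sub, vn, jn, dn)
    vt <- sub$junction_template_nt[sub$name == vn]
    jt <- sub$junction_template_nt[sub$name == jn]
    o <- oracle_decompose(jx, vt, jt, dsub$junction_template_nt)
    d <- decompose(jx, sub[sub$name == vn, ], sub[sub$name == jn, ], dsub)
    expect_equal(d$templated_total, o$templated_total, info = jx)
    expect_equal(d$n_additions_total, o$n_additions_total, info = jx)
  }
})

test_that("component lengths always sum to the junction length", {
  set.seed(17)
  dn <- dset$name
  for (i in 1:150) {
    vn <- sample(g$name[g$segment_type == "V"], 1)
    jn <- sample(g$name[g$segment_type == "J"], 1)
    jx <- random_junction(g, vn, jn, dn, max_len = 60L)
    d <- decompose(jx, g[g$name == vn, ], g[g$name == jn, ], dset)
    expect_equal(d$v_match_len + d$j_match_len + sum(d$d_matches$length) +
                   d$p_nt_5v + d$p_nt_3j + d$p_nt_5d + d$p_nt_3d +
                   d$n_additions_total,
                 nchar(jx))
    expect_equal(sum(nchar(d$n_regions)), d$n_additions_total)
    expect_true(all(c(d$v_match_len, d$j_match_len, d$d_matches$length,
                      d$n_additions_total) >= 0))
  }
})

test_that("inserting a non-templated block between V and J never decreases N additions", {
  # asserted on the D-less gamma locus: with D segments available a block can
  # complete an interior D match that absorbs neighbouring N nucleotides, so
  # the property only holds for blocks that cannot extend templated coverage
  set.seed(23)
  nodset <- dset[0, ]
  for (i in 1:50) {
    vn <- sample(g$name[g$segment_type == "V" & grepl("^TRG", g$name)], 1)
    jn <- sample(c("TRGJP", "TRGJP1", "TRGJ1"), 1)
    jx <- random_junction(g, vn, jn, character(0), max_len = 40L)
    vrow <- g[g$name == vn, ]; jrow <- g[g$name == jn, ]
    d0 <- decompose(jx, vrow, jrow, nodset)
    # insert just after the V match a 4-nt homopolymer that cannot continue
    # the V template match
    vt <- vrow$junction_template_nt
    cut <- d0$v_match_len
    nxt <- if (cut < nchar(vt)) substr(vt, cut + 1, cut + 1) else ""
    x <- setdiff(c("A", "C", "G", "T"),
                 c(nxt, substr(jx, cut + 1, cut + 1)))[1]
    jx2 <- paste0(substr(jx, 1, cut), strrep(x, 4),
                  substr(jx, cut + 1, nchar(jx)))
    d1 <- decompose(jx2, vrow, jrow, nodset)
    expect_gte(d1$n_additions_total, d0$n_additions_total)
  }
})

test_that("junction translation round-trips and flags stops and frame errors", {
  pt <- public_clonotype_table()
  tr <- translate_junction(pt$junction_nt[1])
  expect_equal(tr$junction_aa, "CACDTGGYWDTRQMFF")
  expect_true(tr$productive)
  expect_error(translate_junction(substr(pt$junction_nt[1], 1, 47)),
               "codon-aligned")
  expect_false(translate_junction("TGTGCCTAAACCTTC")$productive)
  expect_error(decompose("TGTNNCC", v2, j3, dset), "non-ACGT")
})

test_that("junction_features resolves alleles, skips unknown calls, empties TRG D", {
  pt <- public_clonotype_table()
  ch <- data.frame(dataset_id = "X", cell_id = c("a", "b", "c"),
                   locus = c("TRD", "TRD", "TRG"),
                   v_call = c("TRDV2*02", "TRDV99", "TRGV9*01"),
                   d_call = "", j_call = c("TRDJ3*01", "TRDJ3", "TRGJP"),
                   junction_nt = c(pt$junction_nt[1], pt$junction_nt[1],
                                   pt$junction_nt[9]),
                   junction_aa = c(pt$junction_aa[1], pt$junction_aa[1],
                                   pt$junction_aa[9]),
                   productive = TRUE, duplicate_count = NA_integer_,
                   stringsAsFactors = FALSE)
  expect_message(feats <- junction_features(ch, g), "no_germline")
  expect_false(feats$no_germline[1])
  expect_true(feats$no_germline[2])
  expect_equal(feats$n_additions_total[1], 0L)
  expect_true(is.na(feats$n_additions_total[2]))
  # TRG decomposition uses no D segments by construction
  d <- decompose(pt$junction_nt[9], g[g$name == "TRGV9", ],
                 g[g$name == "TRGJP", ], dset[0, ])
  expect_equal(nrow(d$d_matches), 0L)
  expect_equal(d$n_additions_total, 0L)
})

test_that("inferred N never exceeds the simulated ground truth (spot check)", {
  sim <- small_sim()
  led <- sim$ledger[sim$ledger$dataset_id == "FT1", ]
  ch <- sim$sc$FT1
  feats <- junction_features(ch, g)
  ok <- !feats$no_germline
  expect_true(all(feats$n_additions_total[ok] <= led$n_ledger[ok]))
  # coverage form of the templated bound: templated + P >= ledger's
  expect_true(all(feats$junction_nt_length[ok] - feats$n_additions_total[ok] >=
                    led$templated_ledger[ok] + led$p_ledger[ok]))
})
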