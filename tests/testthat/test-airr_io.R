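test_that("AIRR round trip preserves populated fields byte-identically", {
  pt <- public_clonotype_table()
  ch <- data.frame(dataset_id = "D1",
                   cell_id = sprintf("cell%02d", seq_len(nrow(pt))),
                   locus = pt$locus, v_call = pt$v_call, d_call = pt$d_call,
                   j_call = pt$j_call, junction_nt = pt$junction_nt,
                   junction_aa = pt$junction_aa, productive = TRUE,
                   duplicate_count = seq_len(nrow(pt)),
                   stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  write_airr(ch, f)
  back <- read_airr(f)
  for (col in c("dataset_id", "cell_id", "locus", "v_call", "j_call",
                "junction_nt", "junction_aa", "productive",
                "duplicate_count"))
    expect_identical(back[[col]], ch[[col]])
})

test_that("AIRR reader maps fields, infers locus and skips foreign loci", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(
    "sequence_id\tv_call\tj_call\tjunction\tjunction_aa\tproductive",
    "s1\tTRDV2*01\tTRDJ3\tTGTGCCTTC\tCAF\tT",
    "s2\tIGHV1-2\tIGHJ4\tTGTGCCTTC\tCAF\tT",
    "s3\tTRAV38-2DV8\tTRDJ1\tTGTGCTTTC\tCAF\tT"), f)
  expect_warning(ch <- read_airr(f), "skipped")
  expect_equal(nrow(ch), 2L)
  expect_equal(ch$locus, c("TRD", "TRD"))
  expect_true(ch$productive[1])
})

test_that("AIRR reader returns empty table for header-only file and errors on missing columns", {
  f <- tempfile(fileext = ".tsv")
  writeLines("sequence_id\tv_call\tj_call\tjunction\tjunction_aa\tproductive", f)
  expect_equal(nrow(read_airr(f)), 0L)
  writeLines("sequence_id\tv_call\tjunction\tjunction_aa\tproductive", f)
  expect_error(read_airr(f), "j_call")
})

test_that("10x contig reader keeps productive high-confidence TRD/TRG rows only", {
  f <- tempfile(fileext = ".csv")
  writeLines(c(
    "barcode,chain,v_gene,d_gene,j_gene,cdr3,cdr3_nt,productive,high_confidence",
    "bc1,TRD,TRDV2,TRDD3,TRDJ3,CAF,TGTGCCTTC,True,True",
    "bc1,TRG,TRGV9,,TRGJP,CAF,TGTGCCTTC,True,True",
    "bc2,TRD,TRDV1,,TRDJ1,CAF,TGTGCCTTC,False,True",
    "bc3,TRB,TRBV5,,TRBJ1,CAF,TGTGCCTTC,True,True",
    "bc4,XYZ,TRDV1,,TRDJ1,CAF,TGTGCCTTC,True,True"), f)
  expect_warning(ch <- read_tenx_contigs(f), "unknown chain")
  expect_equal(nrow(ch), 2L)                     # bc2 unproductive, bc3 TRB out
  expect_equal(sort(unique(ch$cell_id)), "bc1")  # paired barcode kept twice
  expect_setequal(ch$locus, c("TRD", "TRG"))
})

test_that("cell assembly pairs chains, dedupes, caps at two chains per locus", {
  g <- synthetic_germline()
  pt <- public_clonotype_table()
  mk <- function(cell, locus, v, nt, aa, count = 1L)
    list(cell_id = cell, locus = locus, v_call = v, junction_nt = nt,
         junction_aa = aa, count = count)
  cells <- toy_cells(list(
    mk("cellA", "TRD", "TRDV2", pt$junction_nt[1], pt$junction_aa[1], 5L),
    mk("cellA", "TRD", "TRDV1", pt$junction_nt[3], pt$junction_aa[3], 3L),
    mk("cellA", "TRG", "TRGV9", pt$junction_nt[9], pt$junction_aa[9], 4L)))
  expect_equal(cells$cells$n_delta[cells$cells$cell_id == "cellA"], 2L)
  expect_equal(cells$cells$n_gamma[cells$cells$cell_id == "cellA"], 1L)

  # >2 chains of one locus: the two with highest support are kept
  rows <- list(
    mk("cellB", "TRD", "TRDV2", pt$junction_nt[1], pt$junction_aa[1], 10L),
    mk("cellB", "TRD", "TRDV1", pt$junction_nt[3], pt$junction_aa[3], 2L),
    mk("cellB", "TRD", "TRDV3", pt$junction_nt[5], pt$junction_aa[5], 7L))
  cells2 <- toy_cells(rows)
  kept <- cells2$chains[cells2$chains$cell_id == "cellB", ]
  expect_equal(nrow(kept), 2L)
  expect_setequal(sub("\\*.*", "", kept$v_call), c("TRDV2", "TRDV3"))

  # duplicates removed with a warning
  expect_warning(toy_cells(list(
    mk("cellC", "TRD", "TRDV2", pt$junction_nt[1], pt$junction_aa[1]),
    mk("cellC", "TRD", "TRDV2", pt$junction_nt[1], pt$junction_aa[1]))),
    "duplicate")
})

test_that("chains with barcodes absent from metadata are dropped with a count", {
  pt <- public_clonotype_table()
  ch <- data.frame(dataset_id = "TOY", cell_id = c("known", "ghost"),
                   locus = "TRD", v_call = "TRDV2", d_call = "",
                   j_call = "TRDJ3", junction_nt = pt$junction_nt[1],
                   junction_aa = pt$junction_aa[1], productive = TRUE,
                   duplicate_count = NA_integer_, stringsAsFactors = FALSE)
  meta <- data.frame(cell_id = "known", dataset_id = "TOY", subject_id = "S1",
                     age_value = 17, age_unit = "weeks", compartment = "fetal",
                     cluster_label = "c1", group_label = "immature_maturing",
                     effector_type = "none", stringsAsFactors = FALSE)
  expect_message(cells <- assemble_cells(ch, meta), "dropped")
  expect_equal(nrow(cells$chains), 1L)
  # output cell count never exceeds the number of distinct metadata barcodes
  expect_lte(nrow(cells$cells), length(unique(meta$cell_id)))
})

test_that("productivity filter is idempotent and order-independent", {
  pt <- public_clonotype_table()
  ch <- data.frame(dataset_id = "TOY",
                   cell_id = rep(c("c1", "c2"), each = 2),
                   locus = "TRD", v_call = "TRDV2", d_call = "",
                   j_call = "TRDJ3",
                   junction_nt = pt$junction_nt[c(1, 2, 3, 4)],
                   junction_aa = pt$junction_aa[c(1, 2, 3, 4)],
                   productive = c(TRUE, FALSE, FALSE, TRUE),
                   duplicate_count = NA_integer_, stringsAsFactors = FALSE)
  meta <- data.frame(cell_id = c("c1", "c2"), dataset_id = "TOY",
                     subject_id = "S1", age_value = 17, age_unit = "weeks",
                     compartment = "fetal", cluster_label = "c1",
                     group_label = "immature_maturing", effector_type = "none",
                     stringsAsFactors = FALSE)
  a <- assemble_cells(ch, meta)
  b <- assemble_cells(ch[sample(nrow(ch)), ], meta)
  ord <- function(x) x$chains[order(x$chains$cell_id, x$chains$junction_nt), ]
  expect_equal(ord(a)$junction_nt, ord(b)$junction_nt)
  c2 <- assemble_cells(a$chains[, names(ch)], meta)  # re-run on filtered set
  expect_equal(nrow(c2$chains), nrow(a$chains))
})

test_that("assembled chain counts equal the simulator ground-truth ledger", {
  sim <- small_sim()
  cells <- small_cells()
  led <- sim$ledger[sim$ledger$cell_id != "", ]     # sc chains only
  expect_equal(nrow(cells$chains), nrow(led))
  expect_equal(as.vector(table(cells$chains$locus)),
               as.vector(table(led$locus)))
  # per-cell delta counts match the ledger
  led_d <- table(led$cell_id[led$locus == "TRD"])
  expect_equal(sum(cells$cells$n_delta == 2L),
               sum(led_d == 2L))
})

test_that("germline FASTA parses segment types, anchors and TRGJP length", {
  db <- synthetic_germline()
  f <- tempfile(fileext = ".fasta")
  write_germline_fasta(db, f)
  back <- read_germline_fasta(f)
  expect_gte(sum(back$segment_type == "V"), 6L)
  expect_gte(sum(back$segment_type == "D"), 1L)
  expect_gte(sum(back$segment_type == "J"), 4L)
  expect_identical(back$junction_template_nt, db$junction_template_nt)
  # TRGJP is longer than every other TRGJ segment
  trgj <- back[grepl("^TRGJ", back$name), ]
  jp <- nchar(trgj$junction_template_nt[trgj$name == "TRGJP"])
  expect_true(all(jp > nchar(trgj$junction_template_nt[trgj$name != "TRGJP"])))
  # explicit anchor token
  f2 <- tempfile(fileext = ".fasta")
  writeLines(c(">TRGJP|J|anchor=10", "ACCACTGGTTGGTTTGGAAAA"), f2)
  j <- read_germline_fasta(f2)
  expect_equal(j$anchor, 10L)
  expect_equal(j$junction_template_nt, "ACCACTGGTTGGT")
  # V entry lacking a Cys annotation is a format error
  writeLines(c(">TRDV9|V", "TGTGCC"), f2)
  expect_error(read_germline_fasta(f2), "cys")
})
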