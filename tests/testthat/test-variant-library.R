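wt10 <- wild_type("AACCUACGGA", id = "wt10")

test_that("barcode map uses strict-majority consensus and filters reads", {
  seqA <- "AACCGACGGA"  # U5 -> G
  seqB <- "AACCUACGGU"  # A10 -> U
  rec <- tibble::tibble(
    barcode = c("b1", "b1", "b1",          # unanimous
                "b2", "b2", "b2",          # 2/3 majority for seqA
                "b3", "b3",                # tie -> dropped
                "b4", "b4",                # length mismatch -> discarded
                "b5"),
    sequence = c(seqA, seqA, seqA,
                 seqA, seqA, seqB,
                 seqA, seqB,
                 "AACCU", "ACG",
                 "AACCNACGGA")             # non-ACGU -> skipped
  )
  suppressMessages(bm <- build_barcode_map(rec, wt10))
  expect_setequal(bm$barcode, c("b1", "b2"))
  expect_equal(bm$subs[bm$barcode == "b1"], "U5G")
  expect_equal(bm$subs[bm$barcode == "b2"], "U5G")
  expect_equal(attr(bm, "n_dropped_ambiguous"), 1)
  expect_equal(attr(bm, "n_dropped_length"), 2)
  expect_equal(attr(bm, "n_dropped_alphabet"), 1)
  expect_error(build_barcode_map(rec[0, ], wt10), "no DNA-seq records")
})

test_that("T is converted and DNA reads map like RNA reads", {
  rec <- tibble::tibble(barcode = "b1", sequence = "AACCTACGGA")
  bm <- build_barcode_map(rec, wt10)
  expect_equal(bm$subs, "")   # T5 reads as U5 == wild type
})

test_that("cleavage counts aggregate across barcodes sharing a variant", {
  bm <- tibble::tibble(barcode = c("b1", "b2", "b3"),
                       subs = c("U5G", "U5G", "A1C"),
                       n_reads = c(3L, 2L, 1L))
  rna <- tibble::tibble(
    barcode = c("b1", "b1", "b1", "b2", "b3", "zz"),
    cleaved = c(1, 1, 0, 1, 0, 1)
  )
  suppressMessages(cc <- count_cleavage(rna, bm))
  expect_equal(cc$n_cleaved[cc$subs == "U5G"], 3)
  expect_equal(cc$n_total[cc$subs == "U5G"], 4)
  expect_equal(cc$n_total[cc$subs == "A1C"], 1)
  expect_equal(attr(cc, "n_unmapped"), 1)
  expect_warning(count_cleavage(tibble::tibble(barcode = "qq", cleaved = 1),
                                bm),
                 "no RNA-seq barcode matched")
})

test_that("relative activity follows the count-ratio formula", {
  v <- tibble::tibble(
    subs = c("", "U5G", "A1C", "C4G"),
    n_cleaved = c(100L, 50L, 30L, 2L),
    n_total = c(200L, 200L, 60L, 4L)
  )
  act <- compute_ra(v, wt10, min_reads = 5)
  expect_s3_class(act, "coda_activity")
  expect_equal(act$ra[act$subs == ""], 1)            # wild type exactly 1
  expect_equal(act$ra[act$subs == "U5G"], 0.5)
  expect_equal(act$ra[act$subs == "A1C"], 1)         # same proportions as wt
  expect_false("C4G" %in% act$subs)                  # below minimum reads
  expect_error(
    compute_ra(tibble::tibble(subs = "", n_cleaved = 0L, n_total = 10L),
               wt10),
    "RA undefined")
})

test_that("RA is invariant under uniform scaling of all read counts", {
  set.seed(7)
  v <- tibble::tibble(
    subs = c("", "U5G", "A1C"),
    n_cleaved = c(100L, 40L, 7L),
    n_total = c(150L, 90L, 21L)
  )
  a1 <- compute_ra(v, wt10)
  v10 <- dplyr::mutate(v, n_cleaved = n_cleaved * 10L,
                       n_total = n_total * 10L)
  a2 <- compute_ra(v10, wt10)
  expect_equal(a1$ra, a2$ra)
})

test_that("substitution keys are canonicalized with i < j", {
  enc1 <- subs_encode(c(7, 2), c("U", "C"), wt10)
  enc2 <- subs_encode(c(2, 7), c("C", "U"), wt10)
  expect_equal(enc1, enc2)
  expect_equal(enc1, "A2C,C7U")
})

test_that("batch merging averages shared variants and checks the wild type", {
  mk <- function(subs, ra) {
    activity_table(tibble::tibble(subs = subs, n_mut = nchar(subs) > 0,
                                  ra = ra, n_total = 50L,
                                  provenance = "measured"), wt10)
  }
  b1 <- mk(c("", "U5G"), c(1, 0.4))
  b2 <- mk(c("", "U5G", "A1C"), c(1, 0.6, 0.9))
  m <- merge_batches(list(b1, b2))
  expect_equal(m$ra[m$subs == "U5G"], 0.5)
  expect_equal(m$provenance[m$subs == "U5G"], "batch_average")
  expect_equal(m$ra[m$subs == "A1C"], 0.9)
  expect_equal(m$provenance[m$subs == "A1C"], "measured")
  expect_error(merge_batches(list()), "no activity tables")
  b3 <- mk("", 1)
  attr(b3, "wild_type") <- wild_type("AAAAACCCCC")
  expect_error(merge_batches(list(b1, b3)), "different wild-type")
})

test_that("triple reduction divides out a strong third mutation", {
  df <- tibble::tibble(
    subs = c("", "A1C", "C4A", "U5G", "G8C",
             "A1C,C4A,U5G",    # Z = U5G (ra 0.8) qualifies
             "A1C,C4A,G8C",    # Z = G8C (ra 0.4) fails threshold
             "C4A,U5G"),       # direct double blocks (4,5) reductions
    n_mut = c(0L, 1L, 1L, 1L, 1L, 3L, 3L, 2L),
    ra = c(1, 0.3, 0.6, 0.8, 0.4, 0.4, 0.2, 0.5),
    n_total = 100L, provenance = "measured"
  )
  act <- activity_table(df, wt10)
  red <- reduce_triples(act)
  # triple 1: Z=U5G gives RA(A1C,C4A) = 0.4/0.8 = 0.5; Z=C4A (0.6) gives
  # RA(A1C,U5G) = 0.4/0.6; Z=A1C fails (0.3 <= 0.5)
  expect_equal(red$ra[red$subs == "A1C,C4A"], 0.5)
  expect_equal(red$provenance[red$subs == "A1C,C4A"], "reduced_triple")
  expect_equal(red$ra[red$subs == "A1C,U5G"], 0.4 / 0.6)
  # triple 2's only qualifying Z is C4A, but pair (1, 8) -> RA 0.2/0.6
  expect_equal(red$ra[red$subs == "A1C,G8C"], 0.2 / 0.6)
  # the direct double (4,5) is untouched and no reduction targets it
  expect_equal(red$ra[red$subs == "C4A,U5G"], 0.5)
  expect_equal(red$provenance[red$subs == "C4A,U5G"], "measured")
})

test_that("multiple reductions onto the same double key are averaged", {
  df <- tibble::tibble(
    subs = c("", "A1C", "C4A", "U5G", "G8C",
             "A1C,C4A,U5G",   # -> RA(A1C,C4A) = 0.48/0.8 = 0.6
             "A1C,C4A,G8C"),  # -> RA(A1C,C4A) = 0.24/0.6 = 0.4
    n_mut = c(0L, 1L, 1L, 1L, 1L, 3L, 3L),
    ra = c(1, 0.3, 0.3, 0.8, 0.6, 0.48, 0.24),
    n_total = 100L, provenance = "measured"
  )
  red <- reduce_triples(activity_table(df, wt10))
  expect_equal(red$ra[red$subs == "A1C,C4A"], 0.5)
})

test_that("coverage fractions match a brute-force recount", {
  act <- toy_activity(n_doubles = 120, seed = 3)
  cov <- coverage(act)
  L <- attr(act, "wild_type")$length
  expect_equal(cov$n_singles, 3 * L)      # toy table has full singles
  expect_equal(cov$singles, 1)
  brute <- length(unique(act$subs[act$n_mut == 2]))
  expect_equal(cov$n_doubles, brute)
  expect_equal(cov$doubles, brute / (9 * choose(L, 2)))
})

test_that("activity tables round-trip through TSV", {
  act <- toy_activity(n_doubles = 30, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_activity(act, path)
  back <- read_activity(path, attr(act, "wild_type"))
  expect_equal(as.data.frame(back), as.data.frame(act))
})
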