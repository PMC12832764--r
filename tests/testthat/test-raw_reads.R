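test_that("SBC and UMI come from the documented read-1 positions", {
  # 30 A (SBC) + 57 C (linker) + 10 G (UMI) + 3 T tail
  r100 <- paste0(strrep("A", 30), strrep("C", 57), strrep("G", 10),
                 strrep("T", 3))
  out <- extract_sbc_umi(r100)
  expect_identical(out$sbc, strrep("A", 30))
  expect_identical(out$umi, strrep("G", 10))
  expect_true(out$ok)

  short <- extract_sbc_umi(strrep("A", 96))
  expect_false(short$ok)
  expect_identical(short$reason, "short")

  # exactly 97 nt: UMI is the last 10 bases
  r97 <- paste0(strrep("A", 87), strrep("T", 10))
  expect_identical(extract_sbc_umi(r97)$umi, strrep("T", 10))
})

test_that("barcode correction: exact wins, unique 1-mismatch corrects, ties drop", {
  g <- grid_spec(100, 100)
  wl_bc <- c(strrep("A", 30), paste0("C", strrep("A", 29)),
             paste0(strrep("G", 29), "T"))
  wl <- barcode_whitelist(wl_bc, c(1L, 2L, 3L), c(4L, 5L, 6L), g)

  exact <- correct_barcode(strrep("A", 30), wl)
  # A^30 is itself in the whitelist AND at distance 1 from CA^29: exact wins
  expect_identical(exact$status, "exact")
  expect_identical(exact$x_bin, 1L)

  one_off <- correct_barcode(paste0(strrep("G", 29), "A"), wl)
  expect_identical(one_off$status, "corrected")
  expect_identical(one_off$x_bin, 3L)

  # GA^29 is at distance 1 from both A^30 and CA^29: ambiguous, dropped
  amb <- correct_barcode(paste0("G", strrep("A", 29)), wl)
  expect_identical(amb$status, "ambiguous")
  expect_true(is.na(amb$x_bin))

  none <- correct_barcode(paste0("GG", strrep("A", 28)), wl)
  expect_identical(none$status, "nomatch")
})

test_that("barcode correction equals the exhaustive Hamming-scan oracle", {
  set.seed(11)
  g <- grid_spec(64, 64)
  wl_bc <- unique(random_barcodes(300))
  wl <- barcode_whitelist(wl_bc, seq_along(wl_bc) %% 64L,
                          seq_along(wl_bc) %/% 64L, g)
  # queries: whitelist entries, mutated entries, and random noise
  mutate1 <- function(b) {
    p <- sample(30, 1)
    substr(b, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                      substr(b, p, p)), 1)
    b
  }
  queries <- c(sample(wl_bc, 40),
               vapply(sample(wl_bc, 40), mutate1, character(1)),
               random_barcodes(40))
  got <- correct_barcode(queries, wl)
  want_idx <- unname(vapply(queries, oracle_hamming_match, integer(1),
                            wl_barcodes = wl_bc))
  expect_equal(got$x_bin, ifelse(is.na(want_idx), NA_integer_,
                                 wl$x_bin[want_idx]))
  expect_equal(got$y_bin, ifelse(is.na(want_idx), NA_integer_,
                                 wl$y_bin[want_idx]))
})

test_that("UMI deduplication collapses PCR duplicates and conserves tuples", {
  g <- grid_spec(8, 8)
  base <- data.frame(sbc = "B1", x_bin = 1L, y_bin = 2L, gene_id = "g1",
                     stringsAsFactors = FALSE)
  # 3 reads, identical UMI -> one molecule
  r <- cbind(base[rep(1, 3), ], umi = "AAAAAAAAAA")
  expect_equal(dedup_umis(r, g)$umi_count, 1L)
  # UMIs {u1, u1, u2} -> two molecules
  r <- cbind(base[rep(1, 3), ], umi = c("AAAAAAAAAA", "AAAAAAAAAA",
                                        "CCCCCCCCCC"))
  expect_equal(dedup_umis(r, g)$umi_count, 2L)
  # empty input -> empty spot table
  expect_equal(nrow(dedup_umis(r[0, ], g)), 0L)

  # conservation: sum(umi_count) = number of distinct tuples
  set.seed(5)
  n <- 400
  reads <- data.frame(
    sbc = sprintf("B%d", sample(1:6, n, TRUE)),
    gene_id = sprintf("g%d", sample(1:4, n, TRUE)),
    splice_class = sample(c("spliced", "unspliced"), n, TRUE),
    umi = sprintf("U%d", sample(1:8, n, TRUE)),
    stringsAsFactors = FALSE)
  reads$x_bin <- as.integer(factor(reads$sbc)) - 1L
  reads$y_bin <- 0L
  st <- dedup_umis(reads, g)
  expect_equal(sum(st$umi_count),
               nrow(unique(reads[c("sbc", "gene_id", "splice_class", "umi")])))
})

test_that("sequencing saturation follows 1 - unique/assigned", {
  expect_equal(sequencing_saturation(100, 100), 0)
  expect_equal(sequencing_saturation(100, 22), 0.78)
  expect_equal(sequencing_saturation(4, 1), 0.75)
  expect_error(sequencing_saturation(0, 0), "> 0")
})

test_that("simulated error reads are recovered at the analytic 1-error bound", {
  set.seed(101)
  g <- grid_spec(40, 40)
  wl_bc <- unique(random_barcodes(1000))
  wl <- barcode_whitelist(wl_bc, (seq_along(wl_bc) - 1L) %% 40L,
                          (seq_along(wl_bc) - 1L) %/% 40L, g)
  eps <- 0.01
  n <- 1500
  truth <- sample(seq_along(wl_bc), n, replace = TRUE)
  noisy <- vapply(wl_bc[truth], function(b) {
    s <- strsplit(b, "")[[1]]
    flip <- runif(30) < eps
    s[flip] <- vapply(s[flip], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
    paste(s, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  got <- correct_barcode(noisy, wl)
  recovered <- !is.na(got$x_bin) & got$x_bin == wl$x_bin[truth] &
    got$y_bin == wl$y_bin[truth]
  bound <- (1 - eps)^30 + 30 * eps * (1 - eps)^29
  # ambiguity over a 1000-barcode whitelist in 4^30 space is negligible, so
  # recovery should sit at (not materially below) the <=1-error probability
  expect_gte(mean(recovered), bound - 0.02)
})

test_that("demux_reads runs the full read-1 pipeline", {
  g <- grid_spec(10, 10)
  wl <- barcode_whitelist(c(strrep("A", 30), strrep("C", 30)),
                          c(2L, 7L), c(3L, 8L), g)
  mk_read <- function(sbc, umi) paste0(sbc, strrep("T", 57), umi)
  reads <- c(
    mk_read(strrep("A", 30), "GGGGGGGGGG"),   # exact, gene g1
    mk_read(strrep("A", 30), "GGGGGGGGGG"),   # PCR duplicate
    mk_read(paste0("T", strrep("A", 29)), "CCCCCCCCCC"), # corrected, g1
    mk_read(strrep("C", 30), "AAAAAAAAAA"),   # exact, g2
    strrep("A", 50),                          # short
    mk_read(strrep("G", 30), "AAAAAAAAAA")    # nomatch (dist 2+)
  )
  genes <- data.frame(read_id = sprintf("r%d", 1:6),
                      gene_id = c("g1", "g1", "g1", "g2", "g1", "g1"))
  res <- demux_reads(sprintf("r%d", 1:6), reads, genes, wl)
  expect_equal(res$stats$n_short, 1L)
  expect_equal(res$stats$n_nomatch, 1L)
  expect_equal(res$stats$n_assigned, 4L)
  expect_equal(sum(res$spots$umi_count), 3L)  # one duplicate collapsed
  expect_equal(res$stats$saturation, 0.25)
  g1 <- res$spots[res$spots$gene_id == "g1" & res$spots$x_bin == 2L, ]
  expect_equal(g1$umi_count, 2L)
})

test_that("FASTQ reader returns ids and sequences", {
  path <- withr::local_tempfile(fileext = ".fq")
  writeLines(c("@r1 extra", "ACGT", "+", "IIII",
               "@r2", "GGCC", "+", "IIII"), path)
  fq <- read_fastq(path)
  expect_equal(fq$read_id, c("r1", "r2"))
  expect_equal(fq$seq1, c("ACGT", "GGCC"))
})
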