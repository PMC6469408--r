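test_that("identical aligned sequences yield no events", {
  fr <- build_fragment(tss_start = -20L, tss_end = 10L)
  expect_equal(nrow(call_differences(fr)), 0L)
})

test_that("SNVs are called at the correct TSS positions, including the boundary", {
  fr <- build_fragment(tss_start = -20L, tss_end = 10L,
                       snv_positions = c(-20L, -5L, 3L))
  ev <- call_differences(fr)
  expect_equal(ev$tss_position, c(-20L, -5L, 3L))
  expect_equal(ev$kind, rep("SNV", 3))
  expect_true(all(nchar(ev$allele_a) == 1 & ev$allele_a != ev$allele_b))
})

test_that("gap runs collapse to one indel at the leftmost affected base", {
  # species b deletion of 4 bases, TSS -728..-725 within a -730..+9 fragment
  n <- tss_span_length(-730L, 9L)
  set.seed(12)
  a <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  del_idx <- tss_to_index(c(-728L, -727L, -726L, -725L), -730L, 9L)
  a[del_idx] <- c("A", "T", "A", "C")
  b <- a
  b[del_idx] <- "-"
  fr <- sequenced_fragment("GA30092", -730L, 9L, paste(a, collapse = ""),
                           paste(b, collapse = ""))
  ev <- call_differences(fr)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$tss_position, -728L)
  expect_equal(ev$kind, "deletion")
  expect_equal(ev$allele_a, "ATAC")
  expect_equal(ev$allele_b, "-")
  # an insertion in species b anchors to the preceding species-a base
  a2 <- c("A", "C", "G", "T")
  b2 <- c("A", "C", "G", "T", "T", "A")
  a2_aln <- paste(c(a2[1:2], "-", "-", a2[3:4]), collapse = "")
  b2_aln <- paste(c(b2[1:2], b2[5:6], b2[3:4]), collapse = "")
  fr2 <- sequenced_fragment("ins", -2L, 2L, a2_aln, b2_aln)
  ev2 <- call_differences(fr2)
  expect_equal(ev2$kind, "insertion")
  expect_equal(ev2$index, 2L)
  expect_equal(ev2$allele_b, "TA")
})

test_that("ambiguity-code columns are skipped with a warning", {
  fr <- build_fragment(tss_start = -5L, tss_end = 5L, snv_positions = 3L)
  fr$seq_a <- sub("^.", "N", fr$seq_a)
  expect_warning(ev <- call_differences(fr), "ambiguity")
  expect_equal(ev$tss_position, 3L)  # downstream coordinates unaffected
})

test_that("domain classification matches the window and feature rules", {
  expect_equal(classify_domain(-84L), "P")
  expect_equal(classify_domain(200L), "P")
  expect_equal(classify_domain(-200L), "P")
  expect_equal(classify_domain(-348L), "PP")
  expect_equal(classify_domain(-201L), "PP")
  expect_equal(classify_domain(-500L), "PP")   # -500 itself is promoter-proximal
  expect_equal(classify_domain(-501L), "PD")
  expect_equal(classify_domain(-1052L), "PD")
  expect_equal(classify_domain(300L), "other") # downstream, unannotated
  feats <- data.frame(
    feature_type = c("CDS", "UTR5", "neighbor_gene:GA25574", "transcript"),
    tss_start = c(100L, 440L, -1100L, 430L),
    tss_end = c(300L, 460L, -950L, 470L))
  expect_equal(classify_domain(232L, feats[1, ]), "CDS")
  expect_equal(classify_domain(149L, feats[1, ]), "CDS/P")  # CDS inside promoter window
  expect_equal(classify_domain(447L, feats), "T(5'UTR)")
  expect_equal(classify_domain(465L, feats), "T")
  expect_equal(classify_domain(-1081L, feats), "GA25574")
  expect_error(classify_domain(0L), "0")
})

test_that("polymorphism evidence demotes events to shared, reads obey the identity rule", {
  fr <- build_fragment(tss_start = -30L, tss_end = 20L,
                       snv_positions = c(-10L, 5L))
  ev <- call_differences(fr)
  # no evidence: everything fixed
  ev0 <- filter_shared_polymorphisms(ev)
  expect_true(all(ev0$fixed))
  # table evidence holding the species-b allele at one site
  evi <- data.frame(tss_position = -10L,
                    alleles = paste(ev$allele_a[1], ev$allele_b[1], sep = ","))
  ev1 <- filter_shared_polymorphisms(ev, evidence = evi)
  expect_equal(ev1$fixed, c(FALSE, TRUE))
  # a perfect-identity read carrying the alternate allele demotes the event
  ref <- strsplit(gsub("-", "", fr$seq_a), "")[[1]]
  idx <- tss_to_index(5L, -30L, 20L)
  rd <- ref[(idx - 10):(idx + 9)]
  rd[11] <- ev$allele_b[2]
  ev2 <- filter_shared_polymorphisms(ev, reads = paste(rd, collapse = ""),
                                     fragment = fr)
  expect_equal(ev2$fixed, c(TRUE, FALSE))
  # the same read degraded to 85% identity is ignored
  rd85 <- rd
  flip <- c(1:2, 19)  # 3 extra mismatches -> 16/20 = 80% < 90%
  rd85[flip] <- vapply(rd85[flip],
                       function(x) setdiff(c("A", "C", "G", "T"), x)[1], "")
  ev3 <- filter_shared_polymorphisms(ev, reads = paste(rd85, collapse = ""),
                                     fragment = fr)
  expect_true(all(ev3$fixed))
})

test_that("substitution proportions follow the event-count over length rule", {
  subs <- dps_substitutions()
  ga226 <- transform(subs[subs$gene == "GA22690", ], fixed = TRUE)
  ga300 <- transform(subs[subs$gene == "GA30092", ], fixed = TRUE)
  p1 <- substitution_proportion(ga226, N = 1641)
  expect_equal(p1$count, 15L)
  expect_equal(p1$proportion_rounded, 0.009)
  p2 <- substitution_proportion(ga300, N = 1710)
  expect_equal(p2$count, 7L)  # the 4-base deletion counts once
  expect_equal(p2$proportion_rounded, 0.004)
  expect_equal(substitution_proportion(ga226[0, ], N = 100)$proportion, 0)
})

test_that("alignments rebuilt from the bundled event lists are recovered in full", {
  frags <- dps_fragments()
  subs <- dps_substitutions()
  features <- list(
    GA19543 = data.frame(feature_type = "CDS", tss_start = 1100L, tss_end = 1601L),
    GA20504 = data.frame(feature_type = "CDS", tss_start = 400L, tss_end = 659L),
    GA22690 = data.frame(feature_type = "CDS", tss_start = 210L, tss_end = 518L),
    GA24796 = data.frame(feature_type = c("UTR5", "CDS"),
                         tss_start = c(440L, 500L), tss_end = c(460L, 509L)),
    GA30092 = data.frame(feature_type = c("neighbor_gene:GA25574", "CDS"),
                         tss_start = c(-1139L, 100L), tss_end = c(-950L, 528L)))
  for (gi in seq_len(nrow(frags))) {
    g <- frags$gene[gi]
    ev_true <- subs[subs$gene == g, , drop = FALSE]
    n <- frags$span[gi]
    set.seed(300 + gi)
    a <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    b <- a
    if (nrow(ev_true)) {
      idx <- tss_to_index(ev_true$tss_position, frags$tss_start[gi],
                          frags$tss_end[gi])
      for (k in seq_len(nrow(ev_true))) {
        if (ev_true$kind[k] == "deletion") {
          len <- nchar(ev_true$allele_a[k])
          a[idx[k]:(idx[k] + len - 1L)] <-
            strsplit(ev_true$allele_a[k], "")[[1]]
          b[idx[k]:(idx[k] + len - 1L)] <- "-"
        } else {
          a[idx[k]] <- ev_true$allele_a[k]
          b[idx[k]] <- ev_true$allele_b[k]
        }
      }
    }
    fr <- sequenced_fragment(g, frags$tss_start[gi], frags$tss_end[gi],
                             paste(a, collapse = ""), paste(b, collapse = ""),
                             features = features[[g]])
    got <- map_substitutions(fr)$fixed_events
    expect_equal(got$tss_position, ev_true$tss_position, info = g)
    expect_equal(got$kind, ev_true$kind, info = g)
    expect_equal(got$domain, ev_true$domain, info = g)
    expect_equal(got$allele_b, ev_true$allele_b, info = g)
  }
})

test_that("FASTA round trip preserves the fragment and its calls", {
  fr <- build_fragment(gene = "rt", tss_start = -40L, tss_end = 25L,
                       snv_positions = c(-33L, 12L))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_alignment_fasta(fr, path)
  back <- read_alignment_fasta(path, gene = "rt")
  expect_equal(back$seq_a, fr$seq_a)
  expect_equal(back$tss_start, fr$tss_start)
  expect_equal(call_differences(back)$tss_position,
               call_differences(fr)$tss_position)
})
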