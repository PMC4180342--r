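make_aln <- function(rows) {
  out <- rows
  names(out) <- paste0("r", seq_along(rows))
  class(out) <- "alignment"
  out
}

test_that("conservation marks implement the * and + rules", {
  aln <- make_aln(c("LLS", "LLS", "LLS", "LLS", "LLS", "LIS", "LLA"))
  cm <- conservation_marks(aln)
  expect_identical(cm$mark[1], "*")          # 7/7 Leu
  expect_equal(cm$fraction[1], 1)
  expect_identical(cm$mark[2], "+")          # 6 Leu + 1 Ile, both hydrophobic
  expect_equal(cm$fraction[2], 6 / 7)
  expect_identical(cm$mark[3], "")           # variant Ala vs consensus Ser:
  expect_false(cm$hydrophobic[3])            # consensus not hydrophobic
})

test_that("a non-hydrophobic variant forfeits the + mark", {
  aln <- make_aln(c("L", "L", "L", "L", "L", "L", "S"))
  cm <- conservation_marks(aln)
  expect_identical(cm$mark[1], "")
  expect_equal(cm$fraction[1], 6 / 7)
})

test_that("one substitution among seven rows reads as 85% conserved", {
  aln <- make_aln(c("L", "L", "L", "L", "L", "L", "I"))
  cm <- conservation_marks(aln)
  expect_identical(cm$mark[1], "+")
  expect_identical(floor(100 * cm$fraction[1]), 85)
})

test_that("gaps never count toward the consensus", {
  aln <- make_aln(c("L-", "L-", "LA", "L-", "LA"))
  cm <- conservation_marks(aln)
  expect_identical(cm$consensus[2], "A")     # gap is not a residue
  expect_equal(cm$fraction[2], 2 / 5)        # but gaps count as mismatches
  expect_identical(cm$mark[2], "")
})

test_that("marks are invariant under row permutation", {
  set.seed(4)
  aln <- make_alignment(8, 15, c(1, 7 / 8, 6 / 8), seed = 12)
  perm <- make_aln(sample(unclass(aln)))
  expect_identical(conservation_marks(aln)[, -1],
                   conservation_marks(perm)[, -1])
})

test_that("a plus threshold of 1 suppresses + marks entirely", {
  aln <- make_alignment(7, 30, c(1, 6 / 7), seed = 3)
  cm <- conservation_marks(aln, plus_threshold = 1)
  expect_false(any(cm$mark == "+"))
})

test_that("conserved hydrophobic sites are the marked hydrophobic columns", {
  aln <- make_aln(c("LKA", "LKA", "LKA", "LKA", "LKA", "LKA", "IKA"))
  cm <- conservation_marks(aln)
  sites <- conserved_hydrophobic_sites(cm)
  expect_identical(sites, c(1L, 3L))  # K conserved but not hydrophobic
})

test_that("the classifier ranks, weights near peaks, and vetoes", {
  prof_a <- fold_profile("3a", conservation_marks(
    make_aln(c("LAVKI", "LAVKI", "LAVKI", "LAVKI", "LAVKI", "LAVKI",
               "LAVKV"))))
  prof_b <- fold_profile("4b+a", conservation_marks(
    make_aln(c("YAWKI", "YAWKI", "YAWKI", "YAWKI", "YAWKI", "YAWKI",
               "YAWKV"))))
  ## full match to fold A, mismatch at fold B's perfect sites 1 and 3
  cls <- classify_fold("LAVKI", list(prof_a, prof_b))
  expect_identical(cls$fold[1], "3a")
  expect_equal(cls$score[cls$fold == "3a"], 1)
  expect_true(cls$vetoed[cls$fold == "4b+a"])
  ## evidence contributions sum to the reported score
  ev <- attr(cls, "evidence")[["3a"]]
  expect_equal(sum(ev$contribution), cls$score[cls$fold == "3a"])
  ## determinism
  expect_identical(cls, classify_fold("LAVKI", list(prof_a, prof_b)))
})

test_that("sites near F peaks carry double weight", {
  prof <- fold_profile("3a", conservation_marks(
    make_aln(c("LAVKI", "LAVKI", "LAVKI", "LAVKI", "LAVKI", "LAVKI",
               "LAVKI"))))
  ## query mismatching only site 5 (not near the peak at 1)
  s_far <- classify_fold("LAVKG", list(prof), f_peaks = 1L, window = 1)
  ## query mismatching only site 1 (the peak site, double weighted)
  s_near <- classify_fold("GAVKI", list(prof), f_peaks = 1L, window = 1)
  expect_gt(s_far$score, s_near$score)
  expect_error(classify_fold("LAVKI", list()), "no fold profiles")
})

test_that("a query violating one fold's perfect site ranks the other first", {
  prof_a <- fold_profile("A", conservation_marks(
    make_aln(rep("LKKKK", 5))))          # site 1 perfectly L
  prof_b <- fold_profile("B", conservation_marks(
    make_aln(rep("VKKKK", 5))))          # site 1 perfectly V
  cls <- classify_fold("VKKKK", list(prof_a, prof_b))
  expect_identical(cls$fold[1], "B")
  expect_true(cls$vetoed[cls$fold == "A"])
})

test_that("planned alignments realise their conservation fractions", {
  rows <- 10L
  plan <- c(1, 0.9, 0.8, 0.7)
  aln <- make_alignment(rows, 20, plan, seed = 6)
  cm <- conservation_marks(aln)
  expect_equal(cm$fraction, rep_len(plan, 20), tolerance = 1e-9)
  expect_error(make_alignment(5, 10, 0.05, seed = 1), "infeasible")
})
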