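test_that("DSSP three-class mapping and concatenation property", {
  expect_identical(dssp_to_three_class("HGIEB.ST"),
                   c("H", "H", "H", "E", "E", "C", "C", "C"))
  expect_identical(dssp_to_three_class(""), character(0))
  set.seed(7)
  a <- paste(sample(c("H", "G", "I", "E", "B", "S", "T", "."), 30,
                    replace = TRUE), collapse = "")
  b <- paste(sample(c("H", "G", "I", "E", "B", "S", "T", "."), 20,
                    replace = TRUE), collapse = "")
  expect_identical(dssp_to_three_class(paste0(a, b)),
                   c(dssp_to_three_class(a), dssp_to_three_class(b)))
  expect_error(dssp_to_three_class("HX"), "position 2")
  # 3_10-/pi-helix exclusion drops G and I as unassigned
  expect_identical(dssp_to_three_class("HGI", exclude_310_pi = TRUE),
                   c("H", NA, NA))
})

test_that("disorder thresholding uses strict > 0.5", {
  expect_identical(disorder_from_scores(c(0.5, 0.5000001, 0, 1)),
                   c("S", "D", "S", "D"))
  expect_identical(disorder_from_scores(rep(0, 5)), rep("S", 5))
  expect_error(disorder_from_scores(c(0.2, 1.3)), "\\[0, 1\\]")
})

test_that("combine_labels is lossless in both projections", {
  ss <- c("H", "E", "C", "C")
  dd <- c("S", "S", "D", "S")
  comp <- combine_labels(ss, dd)
  expect_identical(comp, c("H^S", "E^S", "C^D", "C^S"))
  expect_identical(sub("\\^.*", "", comp), ss)
  expect_identical(sub(".*\\^", "", comp), dd)
  expect_identical(combine_labels(rep("C", 3), rep("D", 3)),
                   rep("C^D", 3))
  expect_error(combine_labels(ss, dd[1:3]), "length")
})

test_that("build_partitions applies the 35-codon exclusion exactly", {
  set.seed(21)
  genome <- list(gA = sample(fam4$codons, 40, replace = TRUE),
                 gB = sample(fam4$codons, 35, replace = TRUE))
  labels <- list(gA = rep("X", 40), gB = rep("X", 35))
  part <- build_partitions(genome, labels, parse_scheme("X"), FAM)
  # 40-codon gene contributes codons 36..40 only; 35-codon gene none
  expect_equal(sum(part$groups$X$counts["gA", ]), 5)
  expect_equal(sum(part$groups$X$counts["gB", ]), 0)
  expect_equal(part$groups$X$sites$codon_index, 36:40)
  # exclusion idempotence: dropping 35 then 35 again equals once
  trimmed <- lapply(genome, function(x) x)
  part2 <- build_partitions(genome, labels, parse_scheme("X"), FAM,
                            exclude_first_n = 35)
  expect_identical(part$groups$X$counts, part2$groups$X$counts)
  expect_error(build_partitions(genome, labels["gA"],
                                parse_scheme("X"), FAM), "gB")
})

test_that("schemes cover identical codon sets and merge consistently", {
  set.seed(22)
  g <- simulate_genome(n_genes = 12, mean_length = 90,
                       params = truth_params(),
                       grammar = uniform_grammar(c("H", "E", "C")),
                       seed = 23)
  labels <- genome_labels(g)
  schemes <- enumerate_schemes(c("H", "E", "C"))
  expect_length(schemes, 5L) # Bell(3): all set partitions
  # canonical form: sorted groups of sorted labels
  canon <- vapply(schemes, function(s) {
    paste(sort(vapply(split(names(s$map), s$map), function(l)
      paste(sort(l), collapse = ""), character(1))), collapse = "|")
  }, character(1))
  # the 5 groupings: all merged, all separate, and the 3 two-way merges
  expect_setequal(canon, c("CEH", "C|E|H", "C|EH", "CH|E", "CE|H"))
  # identical coverage across schemes (the invariant licensing DIC)
  site_key <- function(part) {
    df <- do.call(rbind, lapply(part$groups, `[[`, "sites"))
    sort(paste(df$gene_id, df$codon_index))
  }
  parts <- lapply(schemes, function(s)
    build_partitions(g, labels, s, FAM))
  keys <- lapply(parts, site_key)
  for (i in 2:length(keys)) expect_identical(keys[[i]], keys[[1]])
  # merged scheme counts equal the sum over separate groups
  merged <- parts[[which(vapply(parts, function(p)
    length(p$groups) == 1, logical(1)))[1]]]
  separate <- parts[[which(vapply(parts, function(p)
    length(p$groups) == 3, logical(1)))[1]]]
  expect_equal(merged$groups[[1]]$counts,
               Reduce(`+`, lapply(separate$groups, `[[`, "counts")),
               ignore_attr = TRUE)
  # ids stable across calls
  expect_identical(vapply(enumerate_schemes(c("H", "E", "C")),
                          `[[`, character(1), "scheme_id"),
                   vapply(schemes, `[[`, character(1), "scheme_id"))
  expect_length(enumerate_schemes(c("S", "D")), 2L)
})

test_that("split_termini labels termini and cores per the stated rules", {
  lens <- c(g1 = 30L)
  segs <- data.frame(gene_id = "g1",
                     start = c(1L, 10L, 20L, 28L),
                     end = c(4L, 15L, 22L, 29L),
                     label = "H", stringsAsFactors = FALSE)
  # min_length 4, terminus 2: length-4 segment has 2+2 and empty core;
  # length-6 has a 2-codon core; length-3 and length-2 are excluded
  tr <- split_termini(segs, lens, terminus_size = 2, min_length = 4)
  expect_identical(tr$g1[1:4], rep("termini", 4))
  expect_identical(tr$g1[10:15],
                   c("termini", "termini", "core", "core",
                     "termini", "termini"))
  expect_true(all(is.na(tr$g1[20:22])))
  expect_true(all(is.na(tr$g1[28:29])))
  # N/C separate mode
  tr2 <- split_termini(segs, lens, terminus_size = 2, min_length = 4,
                       mode = "nc_separate")
  expect_identical(tr2$g1[10:15],
                   c("N-terminus", "N-terminus", "core", "core",
                     "C-terminus", "C-terminus"))
  # included but overlapping termini is an undefined case -> error
  segs5 <- data.frame(gene_id = "g1", start = 1L, end = 5L, label = "H")
  expect_error(split_termini(segs5, lens, terminus_size = 3,
                             min_length = 4), "too short")
})

test_that("positions_2_3_split separates codons 2-3 of long helices", {
  lens <- c(g1 = 20L)
  segs <- data.frame(gene_id = "g1", start = c(1L, 10L),
                     end = c(6L, 14L), label = "H")
  tr <- positions_2_3_split(segs, lens, min_length = 6)
  expect_identical(tr$g1[1:6],
                   c("remainder", "pos23", "pos23", rep("remainder", 3)))
  # length-5 helix excluded entirely
  expect_true(all(is.na(tr$g1[10:14])))
  # conservation: included helix codons all labeled
  expect_equal(sum(!is.na(tr$g1)), 6L)
  expect_equal(sum(tr$g1 == "pos23", na.rm = TRUE), 2L)
})

test_that("segments_from_labels round-trips run structure", {
  labels <- list(gZ = c("H", "H", NA, "C", "C", "C", "H"))
  segs <- segments_from_labels(labels)
  expect_equal(segs$start, c(1L, 4L, 7L))
  expect_equal(segs$end, c(2L, 6L, 7L))
  expect_equal(segs$label, c("H", "C", "H"))
})
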