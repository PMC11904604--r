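test_that("Glu-C digestion reproduces the C-peptide product set", {
  cp <- peptide(cpeptide_sequence())

  zero <- digest(cp, digestion_rule(max_missed_cleavages = 0))
  expect_identical(vapply(zero, function(p) p$sequence, ""),
                   c("E", "AE", "DLQVGQVE", "LGGGPGAGSLQPLALE", "GSLQ"))

  two <- digest(cp, digestion_rule(max_missed_cleavages = 2))
  seqs <- vapply(two, function(p) p$sequence, "")
  expect_true(all(c("LGGGPGAGSLQPLALE", "EAEDLQVGQVE", "DLQVGQVE") %in% seqs))

  # a sequence without cleavage sites comes back whole
  ggg <- digest(peptide("GGG"), digestion_rule(max_missed_cleavages = 0))
  expect_length(ggg, 1L)
  expect_identical(ggg[[1]]$sequence, "GGG")
})

test_that("digestion is span-consistent on random sequences", {
  set.seed(101)
  for (rep in 1:20) {
    parent <- peptide(random_peptide_sequence(sample(8:40, 1)))
    zero <- digest(parent, digestion_rule(max_missed_cleavages = 0,
                                          min_length = 0))
    # concatenating the zero-missed digest reconstructs the parent
    expect_identical(paste(vapply(zero, function(p) p$sequence, ""),
                           collapse = ""),
                     parent$sequence)
    # every k-missed product is the concatenation of k+1 adjacent segments
    all3 <- digest(parent, digestion_rule(max_missed_cleavages = 3,
                                          min_length = 0))
    zero_spans <- t(vapply(zero, function(p) p$origin_span, c(1L, 1L)))
    for (p in all3) {
      i <- match(p$origin_span[1], zero_spans[, 1])
      j <- match(p$origin_span[2], zero_spans[, 2])
      expect_false(is.na(i) || is.na(j) || j < i)
      expect_identical(p$sequence,
                       paste(vapply(zero[i:j], function(q) q$sequence, ""),
                             collapse = ""))
    }
  }
})

test_that("digestion products inherit re-indexed labels", {
  labeled <- cpeptide_labeled()
  products <- digest(labeled, digestion_rule(max_missed_cleavages = 2))
  seqs <- vapply(products, function(p) p$sequence, "")
  qp <- products[[match("LGGGPGAGSLQPLALE", seqs)]]
  expect_identical(qp$origin_span, c(12L, 27L))
  expect_identical(qp$labels$position, 15L)   # parent position 26
  expect_identical(qp$labels$kind, "13C6")
  # the short C-terminal product carries the second label
  gslq <- products[[match("GSLQ", seqs)]]
  expect_identical(gslq$labels$position, 3L)  # parent position 30
})

test_that("peptide and digestion inputs are validated", {
  expect_error(peptide(""), class = "mrmquant_invalid_input")
  expect_error(peptide("ABZ"), class = "mrmquant_invalid_input")
  expect_error(peptide("GG", labels = "5:13C6"),
               class = "mrmquant_invalid_input")
  expect_error(digestion_rule(max_missed_cleavages = 11),
               class = "mrmquant_invalid_input")
  expect_error(fragment_mz(peptide("GG"), fragment_ion("b", 2)),
               class = "mrmquant_invalid_input")
})

test_that("neutral masses match the worked values", {
  mono <- mass_convention("monoisotopic")
  avg <- mass_convention("average")
  expect_equal(peptide_mass(peptide("G"), mono), 75.032, tolerance = 1e-4)
  expect_equal(peptide_mass(peptide("LGGGPGAGSLQPLALE"), mono), 1435.767,
               tolerance = 1e-3)
  expect_equal(peptide_mass(peptide(cpeptide_sequence()), avg), 3020.3,
               tolerance = 2e-4 * 3020)
  # labeled intact C-peptide: the internal-standard molecular weight
  expect_equal(peptide_mass(cpeptide_labeled(), avg), 3032.2,
               tolerance = 2e-4 * 3032)
})

test_that("mass arithmetic matches an independent summation oracle", {
  set.seed(202)
  for (conv in list(mass_convention("monoisotopic"),
                    mass_convention("average"))) {
    for (rep in 1:10) {
      s <- random_peptide_sequence(sample(2:30, 1))
      expect_equal(peptide_mass(peptide(s), conv),
                   oracle_neutral_mass(s, conv), tolerance = 1e-9)
    }
  }
})

test_that("mass additivity holds at every split point", {
  set.seed(303)
  conv_list <- list(mass_convention("monoisotopic"),
                    mass_convention("average"))
  for (conv in conv_list) {
    s <- random_peptide_sequence(18)
    full <- peptide_mass(peptide(s), conv)
    for (i in 1:17) {
      a <- peptide_mass(peptide(substr(s, 1, i)), conv)
      b <- peptide_mass(peptide(substr(s, i + 1, 18)), conv)
      expect_equal(a + b - conv$water_mass, full, tolerance = 1e-9)
    }
  }
})

test_that("fragment m/z reproduces the assay's printed transitions", {
  q <- peptide("LGGGPGAGSLQPLALE")
  ql <- peptide("LGGGPGAGSLQPLALE", labels = "15:13C6")
  avg <- mass_convention("average")
  mono <- mass_convention("monoisotopic")

  expect_equal(round_half_up(fragment_mz(q, fragment_ion("y", 2), avg)),
               261.3)
  expect_equal(round_half_up(fragment_mz(ql, fragment_ion("y", 2), avg)),
               267.3)
  b14 <- fragment_mz(q, fragment_ion("b", 14), mono)
  expect_equal(round_half_up(b14), 1176.6)
  # the label at position 15 lies outside b14: identical m/z
  expect_equal(fragment_mz(ql, fragment_ion("b", 14), mono), b14,
               tolerance = 1e-12)
})

test_that("b/y complementarity holds on random peptides", {
  set.seed(404)
  mono <- mass_convention("monoisotopic")
  for (rep in 1:100) {
    n <- sample(3:25, 1)
    p <- peptide(random_peptide_sequence(n))
    m <- peptide_mass(p, mono)
    i <- sample(n - 1L, 1)
    b_i <- fragment_mz(p, fragment_ion("b", i), mono)
    y_ni <- fragment_mz(p, fragment_ion("y", n - i), mono)
    expect_equal(b_i + y_ni, m + 2 * mono$proton_mass, tolerance = 1e-6)
  }
})

test_that("a label shifts a fragment iff its span covers the position", {
  set.seed(505)
  for (conv in list(mass_convention("monoisotopic"),
                    mass_convention("average"))) {
    n <- 16
    s <- random_peptide_sequence(n)
    pos <- sample(n, 1)
    plain <- peptide(s)
    lab <- peptide(s, labels = sprintf("%d:13C6", pos))
    shift <- conv$label_shift_table[["13C6"]]
    for (i in 1:(n - 1)) {
      for (series in c("b", "y")) {
        ion <- fragment_ion(series, i)
        covered <- if (series == "b") pos <= i else pos > n - i
        delta <- fragment_mz(lab, ion, conv) - fragment_mz(plain, ion, conv)
        expect_equal(delta, if (covered) shift else 0, tolerance = 1e-9)
      }
    }
  }
})
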