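seq_areas <- function(sq) vapply(sq$frames, function(f) sum(f$lesion_mask), numeric(1))
seq_means <- function(sq) vapply(sq$frames, function(f)
  lesion_interior_mean(f$pixels, f$lesion_mask), numeric(1))

test_that("pseudo-sequences have exactly 3 frames with monotone evolution", {
  sq <- make_pseudo_sequence(fixture_lesion(2, seed = 3), seed = 3)
  expect_length(sq$frames, 3)
  areas <- seq_areas(sq)
  means <- seq_means(sq)
  expect_true(all(diff(areas) >= 0))
  expect_true(all(diff(means) <= 0))
  expect_gte(sq$area_growth_per_step, 0.05)
  expect_lte(sq$area_growth_per_step, 0.15)
  expect_gte(sq$darkening_per_step, 0.03)
  expect_lte(sq$darkening_per_step, 0.10)
})

test_that("measured inter-frame ratios fall in the stated bands (seed 7)", {
  sq <- make_pseudo_sequence(fixture_lesion(2, seed = 7), seed = 7)
  areas <- seq_areas(sq)
  means <- seq_means(sq)
  for (k in 2:3) {
    expect_gte(areas[k] / areas[k - 1], 1.05)
    expect_lte(areas[k] / areas[k - 1], 1.15)
    expect_gte(means[k] / means[k - 1], 0.90)
    expect_lte(means[k] / means[k - 1], 0.97)
  }
})

test_that("ratio bands hold across many seeded sequences", {
  for (s in 1:12) {
    base <- generate_lesion(1L + (s %% 2), seed = 300 + s)
    sq <- make_pseudo_sequence(base, seed = s)
    areas <- seq_areas(sq)
    means <- seq_means(sq)
    ar <- areas[-1] / areas[-3]
    mr <- means[-1] / means[-3]
    expect_true(all(ar >= 1.05 & ar <= 1.15))
    expect_true(all(mr >= 0.90 & mr <= 0.97))
  }
})

test_that("zero growth and darkening reproduce the base frame exactly", {
  base <- fixture_lesion(1, seed = 2)
  sq <- make_pseudo_sequence(base, seed = 5, growth = 0, darkening = 0)
  expect_identical(sq$frames[[2]]$pixels, base$pixels)
  expect_identical(sq$frames[[3]]$pixels, base$pixels)
  expect_identical(sq$frames[[3]]$lesion_mask, base$lesion_mask)
})

test_that("sequence construction needs a generator record", {
  bare <- lesionnav:::new_lesion_image(
    array(0.5, c(224, 224, 3)), label = 1L,
    mask = matrix(TRUE, 224, 224))
  expect_error(make_pseudo_sequence(bare, seed = 1), "generator")
})

test_that("sequences are reproducible for equal seeds", {
  a <- make_pseudo_sequence(fixture_lesion(2, seed = 4), seed = 9)
  b <- make_pseudo_sequence(fixture_lesion(2, seed = 4), seed = 9)
  expect_identical(lapply(a$frames, `[[`, "pixels"),
                   lapply(b$frames, `[[`, "pixels"))
})
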