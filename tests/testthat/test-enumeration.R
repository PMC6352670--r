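test_that("closed-shell censuses match the printed tautomer counts", {
  expect_equal(enumerate_closed_shell(0, motifs = FALSE)$names, "a0_b0_c0_d0")
  expect_length(enumerate_closed_shell(2, motifs = FALSE)$names, 7L)
  expect_length(enumerate_closed_shell(4, motifs = FALSE)$names, 49L)
  expect_length(enumerate_closed_shell(6, motifs = FALSE)$names, 74L)
  expect_length(enumerate_closed_shell(8, motifs = FALSE)$names, 24L)
})

test_that("odd levels are rejected as open-shell by parity", {
  expect_error(enumerate_closed_shell(1), "parity")
  expect_error(enumerate_closed_shell(7), "parity")
})

test_that("no closed-shell species exists at levels 10 and 12, even with
           three-electron blocks", {
  expect_length(enumerate_closed_shell(
    10, include_three_electron_blocks = TRUE, motifs = FALSE)$names, 0L)
  expect_length(enumerate_closed_shell(
    12, include_three_electron_blocks = TRUE, motifs = FALSE)$names, 0L)
})

test_that("the seven KP-2e tautomers split 3 single-ring + 4 inter-ring", {
  c2 <- enumerate_closed_shell(2)
  single <- names(Filter(function(t) "single-ring-localized" %in% t,
                         c2$motifs))
  pair <- names(Filter(function(t) "interring-pair" %in% t, c2$motifs))
  expect_length(single, 3L)
  expect_length(pair, 4L)
  # the three localized forms place both removed hydrogens on one unit
  expect_true(all(vapply(single, function(s)
    max(lengths(parse_name(s)$removed)) == 2L, logical(1))))
  expect_true(any(vapply(pair, same_orbit, logical(1), y = "a6_b6_c0_d0")))
})

test_that("every census member is closed-shell and rotation-closed", {
  for (lvl in c(2, 4, 8)) {
    cs <- enumerate_closed_shell(lvl, motifs = FALSE)$names
    for (nm in cs) {
      expect_true(is_closed_shell(nm))
      expect_equal(oxidation_level(nm), lvl)
      for (rot in name_rotations(nm))
        expect_true(format_name(canonical_form(rot)) %in% cs)
    }
  }
})

test_that("the derived building-block library has the printed type counts", {
  lib <- derive_block_library()
  expect_equal(nrow(lib), 9L)
  # 1 reduced / 2 one-electron with dangling double at 2 / 2 at 7 /
  # 3 two-electron (s,s) / 1 two-electron (d,d)
  expect_equal(sum(lib$n_removed == 0), 1L)
  one_e <- lib[lib$n_removed == 1, ]
  expect_equal(sum(one_e$dangling_2 == "double" &
                   one_e$dangling_7 == "single"), 2L)
  expect_equal(sum(one_e$dangling_2 == "single" &
                   one_e$dangling_7 == "double"), 2L)
  # the one-electron states are exactly {N1} and {O6}, never {O5}
  expect_setequal(unique(one_e$state), c("1", "6"))
  two_e <- lib[lib$n_removed == 2, ]
  expect_equal(sum(two_e$dangling_2 == "single" &
                   two_e$dangling_7 == "single"), 3L)
  dd <- two_e[two_e$dangling_2 == "double" & two_e$dangling_7 == "double", ]
  expect_equal(nrow(dd), 1L)
  expect_equal(dd$state, "16")
})

test_that("exactly one three-electron block exists, dangling double at 7", {
  lib3 <- derive_block_library(include_three_electron_blocks = TRUE)
  extra <- lib3[lib3$n_removed == 3, ]
  expect_equal(nrow(extra), 1L)
  expect_equal(extra$state, "156")
  expect_equal(extra$dangling_2, "single")
  expect_equal(extra$dangling_7, "double")
})

test_that("open-shell enumeration counts rotation orbits with no valence
           constraint", {
  expect_length(enumerate_open_shell(1), 3L)
  expect_equal(enumerate_open_shell(0), "a0_b0_c0_d0")
  expect_equal(enumerate_open_shell(12), "a156_b156_c156_d156")
  expect_equal(sum(vapply(0:12, function(l)
    length(enumerate_open_shell(l)), integer(1))), 1044L)
})

test_that("closed-shell detection matches hand-checked species", {
  expect_true(is_closed_shell("a6_b6_c0_d0"))
  expect_false(is_closed_shell("a1_b0_c0_d0"))   # odd removed-H count
  expect_false(is_closed_shell("a6_b0_c6_d0"))   # opposite 1e rings
})

test_that("building-block composition and whole-graph matching agree on all
           4096 state assignments", {
  for (nm in all_state_assignments()) {
    expect_identical(
      composable_from_blocks(nm, include_three_electron_blocks = TRUE),
      is_closed_shell(nm))
  }
})

test_that("Burnside orbit counts over valid configurations equal census
           sizes", {
  states <- kporphyrin:::.kp_state_sets()
  masks <- vapply(states, function(s)
    sum(kporphyrin:::.kp_site_bit[s]), numeric(1))
  feasible <- function(tuple_idx) {
    nm <- kporphyrin:::.kp_new_name(states[tuple_idx])
    sum(lengths(states[tuple_idx])) <= 12 &&
      max(lengths(states[tuple_idx])) <= 2 &&
      is_closed_shell(nm)
  }
  for (lvl in c(2, 4, 6, 8)) {
    fixed <- numeric(4)
    for (ia in 1:8) for (ib in 1:8) for (ic in 1:8) for (id in 1:8) {
      tp <- c(ia, ib, ic, id)
      if (sum(lengths(states[tp])) != lvl) next
      if (max(lengths(states[tp])) > 2) next
      if (!feasible(tp)) next
      fixed[1] <- fixed[1] + 1                              # identity
      if (ia == ib && ib == ic && ic == id) {
        fixed[2] <- fixed[2] + 1; fixed[4] <- fixed[4] + 1  # rot 1, rot 3
      }
      if (ia == ic && ib == id) fixed[3] <- fixed[3] + 1    # rot 2
    }
    burnside <- sum(fixed) / 4
    expect_equal(burnside,
                 length(enumerate_closed_shell(lvl, motifs = FALSE)$names))
  }
})

test_that("the KP-4e census restricted to four one-electron rings is the
           six-membered macrocyclic list", {
  cs4 <- enumerate_closed_shell(4, motifs = FALSE)$names
  sub <- Filter(function(nm)
    all(lengths(parse_name(nm)$removed) == 1L), cs4)
  listed <- c("a1_b1_c1_d1", "a1_b1_c1_d6", "a1_b1_c6_d6", "a1_b6_c1_d6",
              "a1_b6_c6_d6", "a6_b6_c6_d6")
  expect_length(sub, 6L)
  for (nm in listed)
    expect_true(any(vapply(sub, same_orbit, logical(1), y = nm)))
})

test_that("conjugation motifs match the described structures", {
  expect_true("interring-pair" %in% classify_motifs("a6_b6_c0_d0"))
  expect_true("three-ring-chain" %in% classify_motifs("a6_b16_c6_d0"))
  expect_equal(classify_motifs("a16_b56_c16_d56"),
               "alternating-localized-quinonoid")
  expect_equal(classify_motifs("a16_b0_c0_d0"), "single-ring-localized")
  expect_true("macrocyclic-conjugated" %in% classify_motifs("a6_b6_c6_d6"))
  expect_error(classify_motifs("a1_b0_c0_d0"), "open-shell")
})
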