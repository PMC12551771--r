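test_that("default tables are self-consistent and carry the pinned O2 rate constants", {
  sp <- default_species()
  rx <- default_reactions()
  expect_silent(validate_chemistry(sp, rx))
  expect_true(all(c("e_aq", "OH", "H", "H2", "H2O2", "H3O+", "OH-", "O-",
                    "O2", "O2-", "HO2", "HO2-") %in% sp$name))
  expect_identical(sp$name[sp$representation == "continuum"], "O2")
  expect_equal(rx$k[rx$label == "R1"], 1.27e10)
  expect_equal(rx$k[rx$label == "R2"], 1.48e10)
  expect_identical(rx$type[rx$label %in% c("R1", "R2")],
                   rep("pseudo_first_order", 2))
  # shipped CSV copies match the in-code defaults
  ext <- system.file("extdata", package = "uhdrchem")
  expect_equal(read.csv(file.path(ext, "default_species.csv"))$D_m2s, sp$D_m2s)
  expect_equal(read.csv(file.path(ext, "default_reactions.csv"))$k, rx$k)
})

test_that("validation rejects malformed tables naming the offending entry", {
  sp <- default_species()
  expect_error(validate_chemistry(sp[0, ], default_reactions()), "empty")
  bad <- default_reactions()
  bad$r2[bad$label == "R3"] <- "XYZ"
  expect_error(validate_chemistry(sp, bad), "R3.*XYZ")
  bad <- default_reactions()
  bad$k[bad$label == "r13"] <- -1
  expect_error(validate_chemistry(sp, bad), "r13")
  bad <- default_reactions()
  bad$type[bad$label == "R1"] <- "second_order"
  expect_error(validate_chemistry(sp, bad), "R1")
  sp2 <- rbind(sp, sp[1, ])
  expect_error(validate_chemistry(sp2, default_reactions()), "duplicate")
})

test_that("every default reaction conserves H, O and charge up to implicit water", {
  expect_true(check_balance(default_species(), default_reactions()))
  broken <- data.frame(label = "bad", r1 = "OH", r2 = "OH", p1 = "H2O2",
                       p2 = "H2", p3 = NA, k = 1, type = "second_order")
  expect_error(check_balance(default_species(), broken), "bad")
})

test_that("Smoluchowski radius mapping is exact and round-trips", {
  expect_equal(effective_reaction_radius(0, 7.1e-9), 0)
  expect_equal(effective_reaction_radius(1.1e10, 7.1e-9), 0.2047,
               tolerance = 1e-3)
  set.seed(1)
  k <- 10^runif(20, 6, 11)
  D <- 10^runif(20, -9.5, -8)
  expect_equal(smoluchowski_rate(effective_reaction_radius(k, D), D), k,
               tolerance = 1e-12)
  expect_error(effective_reaction_radius(1e9, 0), "D_mutual")
  expect_error(effective_reaction_radius(-1, 1e-9), "k must be")
})

test_that("derived encounter radii regenerate the per-pair rate constant", {
  chem <- default_chemistry()
  so <- chem$so
  expect_equal(smoluchowski_rate(so$R_eff_nm, so$D_mutual_m2s), so$k_pair,
               tolerance = 1e-9)
  # identical reactants carry the doubled (per-pair) constant
  same <- so$r1 == so$r2
  expect_equal(so$k_pair[same], 2 * so$k[same])
  expect_equal(so$k_pair[!same], so$k[!same])
})
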