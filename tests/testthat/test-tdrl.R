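test_that("single TDRL rounds replay the documented rearrangements", {
  wancy <- strsplit("WANCY", "")[[1]]
  d1 <- apply_tdrl(wancy, list(list(block = c(1, 5),
                                    losses = c(2, 3, 4, 6, 10))))
  expect_identical(paste(unclass(d1), collapse = ""), "WYANC")
  expect_true(verify_scenario(
    tdrl_scenario(wancy,
                  list(list(block = c(1, 5), losses = c(2, 3, 4, 6, 10))),
                  d1)))

  d2 <- apply_tdrl(wancy, list(list(block = c(1, 5),
                                    losses = c(2, 6, 8, 10))))
  expect_identical(paste(unclass(d2), collapse = ""), "WNCYAC")

  d0 <- apply_tdrl(wancy, list())
  expect_identical(paste(unclass(d0), collapse = ""), "WANCY")

  # a scenario whose stated derived order is wrong does not verify
  expect_false(verify_scenario(tdrl_scenario(
    wancy, list(list(block = c(1, 5), losses = c(2, 6, 8, 10))), "WYANC")))
})

test_that("apply_tdrl enforces the letter-retention invariant", {
  wancy <- strsplit("WANCY", "")[[1]]
  expect_error(apply_tdrl(wancy, list(list(block = c(1, 2),
                                           losses = c(1, 3)))),
               "leaves no copy")
  expect_error(apply_tdrl(wancy, list(list(block = c(4, 2), losses = c()))),
               "block")
  expect_error(apply_tdrl(wancy, list(list(block = c(1, 2),
                                           losses = c(8)))),
               "loss|bounds")
})

test_that("minimal_scenarios agrees with exhaustive enumeration on ABC", {
  src <- strsplit("ABC", "")[[1]]
  reach1 <- oracle_reach_one(src)
  alphabet <- c("A", "B", "C")
  targets <- character(0)
  for (len in 3:5) {
    grid <- do.call(expand.grid, rep(list(alphabet), len))
    targets <- c(targets, apply(grid, 1, paste, collapse = ""))
  }
  # restrict to targets containing every letter (retention invariant)
  targets <- targets[vapply(targets, function(t)
    all(alphabet %in% strsplit(t, "")[[1]]), logical(1))]
  for (tgt in targets) {
    want <- oracle_min_rounds("ABC", tgt, max_rounds = 2,
                              reach1_cache = reach1)
    got <- minimal_scenarios(src, strsplit(tgt, "")[[1]], max_rounds = 2)
    if (is.na(want)) {
      expect_length(got, 0)
    } else {
      expect_identical(attr(got, "min_rounds"), want, label = tgt)
      for (sc in got) {
        expect_true(verify_scenario(sc), label = tgt)
        expect_identical(paste(unclass(sc$derived), collapse = ""), tgt)
        expect_length(sc$rounds, want)
      }
    }
  }
})

test_that("minimal_scenarios agrees with the oracle on sampled ABCD targets", {
  src <- strsplit("ABCD", "")[[1]]
  reach1 <- oracle_reach_one(src)
  set.seed(41)
  for (i in 1:15) {
    len <- sample(4:7, 1)
    tgt <- paste(c(c("A", "B", "C", "D"),
                   sample(c("A", "B", "C", "D"), len - 4, replace = TRUE))[
                     sample(len)], collapse = "")
    want <- oracle_min_rounds("ABCD", tgt, max_rounds = 2,
                              reach1_cache = reach1)
    got <- minimal_scenarios(src, strsplit(tgt, "")[[1]], max_rounds = 2)
    if (is.na(want)) {
      expect_length(got, 0)
    } else {
      expect_identical(attr(got, "min_rounds"), want, label = tgt)
      expect_true(all(vapply(got, verify_scenario, logical(1))))
    }
  }
})

test_that("minimal_scenarios agrees with the oracle from WANCY", {
  src <- strsplit("WANCY", "")[[1]]
  reach1 <- oracle_reach_one(src)
  named <- c("WYANC", "WNCYAC", "WNCYAA", "WANCY")
  set.seed(53)
  rand <- vapply(1:12, function(i) {
    len <- sample(5:7, 1)
    paste(c(src, sample(src, len - 5, replace = TRUE))[sample(len)],
          collapse = "")
  }, character(1))
  for (tgt in unique(c(named, rand))) {
    want <- oracle_min_rounds("WANCY", tgt, max_rounds = 2,
                              reach1_cache = reach1)
    got <- minimal_scenarios(src, strsplit(tgt, "")[[1]], max_rounds = 2)
    if (is.na(want)) {
      expect_length(got, 0)
    } else {
      expect_identical(attr(got, "min_rounds"), want, label = tgt)
      for (sc in got) {
        expect_true(verify_scenario(sc))
        expect_identical(paste(unclass(sc$derived), collapse = ""), tgt)
      }
    }
  }
})

test_that("reference cluster scenarios replay and are minimal", {
  ref <- liparis_tdrl_scenarios()
  expect_setequal(names(ref), c("WYANC", "WNCYAC", "WNCYAA"))
  for (nm in names(ref)) {
    expect_true(verify_scenario(ref[[nm]]), label = nm)
    expect_identical(paste(unclass(ref[[nm]]$derived), collapse = ""), nm)
  }
  expect_length(ref$WYANC$rounds, 1)
  expect_length(ref$WNCYAC$rounds, 1)
  expect_length(ref$WNCYAA$rounds, 2)
  # these round counts are the true minima
  src <- strsplit("WANCY", "")[[1]]
  for (nm in names(ref)) {
    ms <- minimal_scenarios(src, strsplit(nm, "")[[1]], max_rounds = 2)
    expect_identical(attr(ms, "min_rounds"),
                     length(ref[[nm]]$rounds), label = nm)
  }
})

test_that("pattern classification and cluster extraction work on fixtures", {
  expect_identical(classify_pattern(strsplit("WANCY", "")[[1]]), "WANCY")
  expect_identical(classify_pattern(strsplit("WNCYAA", "")[[1]]), "WNCYAA")
  expect_identical(classify_pattern(c("W", "A", "N")), "OTHER")
  fx <- liparis_fixtures()
  expect_identical(classify_pattern(extract_cluster(fx$chefuensis)),
                   "WYANC")
  expect_identical(classify_pattern(extract_cluster(fx$tanakae)),
                   "WNCYAA")
  sim <- generate_record(generator_spec(seed = 2, pattern = "WNCYAC"))
  expect_identical(classify_pattern(extract_cluster(sim$record)),
                   "WNCYAC")
})

test_that("scenario lists serialize to JSON with verifiable content", {
  src <- strsplit("WANCY", "")[[1]]
  ms <- minimal_scenarios(src, strsplit("WYANC", "")[[1]], max_rounds = 2)
  p <- file.path(tempdir(), "scen.json")
  write_scenarios(ms, p)
  back <- jsonlite::read_json(p)
  expect_length(back, length(ms))
  for (b in back) {
    expect_identical(b$source, "WANCY")
    expect_identical(b$derived, "WYANC")
    rounds <- lapply(b$rounds, function(rd)
      list(block = unlist(rd$block), losses = unlist(rd$losses)))
    replay <- apply_tdrl(b$source, rounds)
    expect_identical(paste(unclass(replay), collapse = ""), b$derived)
  }
})
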