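# Feature codes, feature perception, model fitting and screening.

test_that("feature codes parse to the published multisets", {
  expect_equal(parse_feature_code("AANNR"), c(A = 2L, R = 1L, N = 2L))
  expect_equal(parse_feature_code("AAAADH"), c(A = 4L, D = 1L, H = 1L))
  expect_equal(parse_feature_code(""), setNames(integer(0), character(0)))
  expect_error(parse_feature_code("AXZ"), "unknown feature letter")
})

test_that("ligand feature perception follows the rule table", {
  b <- benzene_mol()
  fb <- perceive_ligand_features(b, 1)
  expect_equal(nrow(fb), 1L)               # exactly one ring feature
  expect_equal(fb$kind, "R")
  expect_equal(c(fb$x, fb$y, fb$z), c(0, 0, 0), tolerance = 1e-9)

  ace <- parse_smiles("CC(=O)[O-]", "acetate")
  ace$conformers <- list(cbind(c(0, 1.5, 2.2, 2.2), c(0, 0, 1, -1), 0))
  fa <- perceive_ligand_features(ace, 1)
  expect_true("N" %in% fa$kind)            # carboxylate -> negative ionizable
  ncent <- fa[fa$kind == "N", ]
  expect_equal(c(ncent$x, ncent$y),
               colMeans(ace$conformers[[1]][2:4, 1:2]), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(perceive_ligand_features(ace, 2), "no conformer")
})

test_that("feature points co-move under rigid motion of the conformer", {
  lib <- gen_toy_library(5, seed = 31)
  for (m in lib) {
    f1 <- perceive_ligand_features(m, 1)
    if (!nrow(f1)) next
    m2 <- m
    m2$conformers[[1]] <- rigid_move(m$conformers[[1]], 0.9, c(2, 2, -1))
    f2 <- perceive_ligand_features(m2, 1)
    expect_equal(f2$kind, f1$kind)
    moved <- rigid_move(as.matrix(f1[, c("x", "y", "z")]), 0.9, c(2, 2, -1))
    expect_equal(as.matrix(f2[, c("x", "y", "z")]), moved, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

# model whose features sit exactly on a ligand's perceived points
self_model <- function(mol, idx = NULL, ...) {
  pts <- perceive_ligand_features(mol, 1)
  if (is.null(idx)) idx <- seq_len(nrow(pts))
  pharmacophore_model("self", pts[idx, c("kind", "x", "y", "z")], ...)
}

test_that("FitValue is exact for aligned and tolerance-displaced features", {
  # 6 unit-weight features at known positions, ligand points exactly there
  pts <- data.frame(kind = c("A", "A", "D", "H", "R", "N"),
                    x = c(0, 3, 0, 3, 1.5, 1.5),
                    y = c(0, 0, 3, 3, 1.5, -1.5), z = c(0, 0, 0, 0, 1, -1))
  model <- pharmacophore_model("m6", pts)
  # synthetic ligand whose feature points reproduce pts: use the points
  # directly through a stub molecule with matching perception
  lig <- parse_smiles("OC(=O)CC(N)CO", "stub")
  # bypass perception: fit a point set by constructing a molecule whose
  # features land on the targets is fragile; instead check the scoring
  # arithmetic through the internal assignment scorer
  asg <- seq_len(6)
  xyz <- as.matrix(pts[, c("x", "y", "z")])
  val <- evscreen:::.score_assignment(asg, model, pts, xyz)
  expect_equal(val, 6, tolerance = 1e-9)
  # one feature displaced by exactly its tolerance contributes 0
  pts2 <- pts
  pts2$z[1] <- pts2$z[1] + model$features$tolerance[1]
  # displacement orthogonal to the plane of the remaining matches changes
  # the optimal alignment; evaluate the term formula directly instead
  d <- model$features$tolerance
  terms <- pmax(0, 1 - (c(d[1], rep(0, 5)) / d)^2)
  expect_equal(sum(terms), 5)
})

test_that("fitting a ligand to its own feature geometry scores the maximum", {
  lib <- gen_toy_library(40, seed = 41)
  picked <- 0
  for (m in lib) {
    pts <- perceive_ligand_features(m, 1)
    if (nrow(pts) < 4) next
    model <- self_model(m, idx = seq_len(min(5, nrow(pts))))
    fit <- fit_to_model(m, model)
    expect_true(fit$matched)
    expect_equal(fit$fit_value, nrow(model$features), tolerance = 1e-6)
    picked <- picked + 1
    if (picked >= 5) break
  }
  expect_gte(picked, 3)
})

test_that("FitValue is invariant under rigid motion of the ligand", {
  lib <- gen_toy_library(30, seed = 43)
  m <- NULL
  for (cand in lib) if (nrow(perceive_ligand_features(cand, 1)) >= 4) {
    m <- cand; break
  }
  model <- self_model(m, idx = 1:4)
  f1 <- fit_to_model(m, model)
  m2 <- m
  m2$conformers[[1]] <- rigid_move(m$conformers[[1]], 1.1, c(-4, 2, 7))
  f2 <- fit_to_model(m2, model)
  expect_equal(f2$fit_value, f1$fit_value, tolerance = 1e-6)
})

test_that("fit_to_model equals exhaustive assignment enumeration", {
  # small models vs ligand point sets: compare against an independent
  # brute-force over all injective kind-respecting assignments
  lib <- gen_toy_library(25, seed = 47)
  checked <- 0
  for (m in lib) {
    pts <- perceive_ligand_features(m, 1)
    if (nrow(pts) < 3 || nrow(pts) > 6) next
    target <- self_model(m, idx = seq_len(min(4, nrow(pts))),
                         min_features_to_match = 3)
    got <- fit_to_model(m, target)
    # brute force
    nf <- nrow(target$features)
    best <- -10
    xyz <- m$conformers[[1]]
    for (sz in nf:3) {
      for (S in utils::combn(nf, sz, simplify = FALSE)) {
        cand_pts <- lapply(S, function(f)
          which(pts$kind == target$features$kind[f]))
        grid <- expand.grid(cand_pts)
        if (!nrow(grid)) next
        for (r in seq_len(nrow(grid))) {
          row <- unlist(grid[r, ])
          if (anyDuplicated(row)) next
          asg <- rep(NA_integer_, nf); asg[S] <- row
          v <- evscreen:::.score_assignment(asg, target, pts, xyz)
          if (!is.na(v) && v > best) best <- v
        }
      }
    }
    expect_equal(got$fit_value, best, tolerance = 1e-9)
    checked <- checked + 1
    if (checked >= 6) break
  }
  expect_gte(checked, 3)
})

test_that("unmatched ligands carry exactly the -10 sentinel", {
  # a model far outside any ligand's geometry span cannot be matched:
  # demand kinds the ligand does not have
  model <- pharmacophore_model("impossible",
    data.frame(kind = c("P", "P", "P"), x = c(0, 5, 9), y = 0, z = 0))
  m <- benzene_mol()
  fit <- fit_to_model(m, model)
  expect_false(fit$matched)
  expect_identical(fit$fit_value, FIT_SENTINEL)
  expect_identical(FIT_SENTINEL, -10)
  expect_error(fit_to_model(m, pharmacophore_model("tiny",
    data.frame(kind = c("A", "D"), x = c(0, 1), y = 0, z = 0))),
    "at least 3")
})

test_that("exclusion spheres reject clashing placements", {
  lib <- gen_toy_library(30, seed = 53)
  m <- NULL
  for (cand in lib) if (nrow(perceive_ligand_features(cand, 1)) >= 4) {
    m <- cand; break
  }
  base <- self_model(m, idx = 1:4)
  f_ok <- fit_to_model(m, base)
  expect_true(f_ok$matched)
  # a huge exclusion sphere centred on the matched ligand swallows every
  # placement
  blocked <- pharmacophore_model("blocked", base$features,
    exclusion = data.frame(x = mean(base$features$x),
                           y = mean(base$features$y),
                           z = mean(base$features$z), radius = 50))
  f_no <- fit_to_model(m, blocked)
  expect_false(f_no$matched)
  expect_identical(f_no$fit_value, -10)
})

test_that("screen_library applies the ceiling rule and drops sentinels", {
  lib <- gen_toy_library(200, seed = 59)
  m <- NULL
  for (cand in lib) if (nrow(perceive_ligand_features(cand, 1)) >= 4) {
    m <- cand; break
  }
  model <- self_model(m, idx = 1:4, min_features_to_match = 3)
  kept <- screen_library(lib, model, keep_fraction = 0.01)
  expect_lte(nrow(kept), ceiling(0.01 * 200))
  expect_true(all(kept$matched))
  expect_true(all(kept$fit_value > -10))
  # kept set equals the top-m of independently recomputed fit values
  all_tab <- attr(kept, "all")
  recomputed <- vapply(lib, function(x) fit_to_model(x, model)$fit_value, 0)
  ord <- order(-recomputed, vapply(lib, function(x) x$id, ""))
  expect_equal(sort(kept$fit_value),
               sort(recomputed[ord][seq_len(nrow(kept))]), tolerance = 1e-9)
  # impossible model: everything fails, empty kept list plus warning
  imp <- pharmacophore_model("imp",
    data.frame(kind = c("P", "P", "P"), x = c(0, 4, 8), y = 0, z = 0))
  expect_warning(none <- screen_library(lib[1:20], imp, keep_fraction = 0.1),
                 "no ligand matched")
  expect_equal(nrow(none), 0)
  expect_warning(screen_library(list(), model), "empty")
})

test_that("complex-derived models keep only protein-supported features", {
  # synthetic complex: ligand with a donor/acceptor pair near a polar
  # protein atom and a hydrophobic tail with no apolar pocket
  lig <- parse_smiles("OCCCC", "lig")
  lig$conformers <- list(cbind(c(0, 1.4, 2.8, 4.2, 5.6), 0, 0))
  prot <- data.frame(element = c("N", "O", "N"),
                     x = c(0.5, -1.0, 0.0), y = c(2.0, 1.5, -2.0),
                     z = 0, resid = "SER", elety = c("N", "OG", "ND1"))
  s <- structure_model("cplx", cbind(0, 0, 1:4), ligand = lig,
                       protein_atoms = prot)
  model <- derive_model_from_complex(s)
  expect_true(all(model$features$kind %in% c("A", "D")))
  expect_false("H" %in% model$features$kind)   # no apolar pocket
  expect_lte(nrow(model$features), 6)
  # contact counting matches a brute-force distance loop
  pts <- perceive_ligand_features(lig, 1)
  for (i in seq_len(nrow(pts))) {
    if (pts$kind[i] %in% c("A", "D")) {
      dd <- sqrt((prot$x - pts$x[i])^2 + (prot$y - pts$y[i])^2 +
                   (prot$z - pts$z[i])^2)
      supported <- any(dd <= 3.5)
      expect_equal(any(abs(model$features$x - pts$x[i]) < 1e-9 &
                         model$features$kind == pts$kind[i]), supported)
    }
  }
  expect_error(derive_model_from_complex(
    structure_model("empty", cbind(0, 0, 1:4))), "no ligand")
})

test_that("cross-validated pharmacophore AUC behaves at its limits", {
  lib <- gen_toy_library(60, seed = 61)
  m <- NULL
  for (cand in lib) if (nrow(perceive_ligand_features(cand, 1)) >= 4) {
    m <- cand; break
  }
  model <- self_model(m, idx = 1:4, min_features_to_match = 3)
  fv <- vapply(lib, function(x) fit_to_model(x, model)$fit_value, 0)
  # labels that follow the fit values perfectly -> AUC near 1
  labels <- as.integer(fv >= stats::median(fv))
  if (length(unique(labels)) == 2 && min(table(labels)) >= 5) {
    auc <- validate_model(model, lib, labels, folds = 5, seed = 7)
    expect_gt(auc, 0.9)
  }
  # all-sentinel fit values are uninformative: AUC 0.5
  tab <- score_table(sprintf("x%02d", 1:40), "FitValue",
                     matrix(rep(-10, 40), ncol = 1),
                     rep(c(1L, 0L), 20))
  expect_equal(cv_auc(tab, "FitValue", folds = 5, seed = 1), 0.5,
               tolerance = 1e-9)
})

test_that("pharmacophore JSON round-trips the model", {
  pts <- data.frame(kind = c("A", "D", "R", "N"),
                    x = c(0, 2, 4, 1), y = c(1, 0, 2, 3), z = c(0, 1, 0, 2),
                    tolerance = c(1.6, 1.6, 2.0, 1.2),
                    weight = c(1, 1, 2, 1))
  excl <- data.frame(x = 9, y = 9, z = 9, radius = 2.5)
  model <- pharmacophore_model("rt", pts, excl, min_features_to_match = 3)
  path <- tempfile(fileext = ".json")
  write_pharmacophore_json(model, path)
  back <- read_pharmacophore_json(path)
  expect_equal(back$features, model$features, tolerance = 1e-12)
  expect_equal(back$exclusion$radius, 2.5)
  expect_equal(back$min_features_to_match, 3L)
})
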