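test_that("forest-map aggregation computes block means and driver modes", {
  # half the subpixels lost at full cover -> 50% loss
  lm_ <- matrix(rep(c(1, 0), 8), 4, 4)
  cv <- matrix(1, 4, 4)
  dv <- matrix(ifelse(lm_ == 1, "fire", NA), 4, 4)
  agg <- aggregate_forest_maps(lm_, cv, dv, block = 4)
  expect_equal(agg$loss_pct[1, 1], 50)
  expect_equal(agg$cover_pct[1, 1], 100)
  expect_equal(agg$driver[1, 1], "fire")

  # no loss: 0% and undefined driver
  agg0 <- aggregate_forest_maps(matrix(0, 4, 4), cv,
                                matrix(NA_character_, 4, 4), 4)
  expect_equal(agg0$loss_pct[1, 1], 0)
  expect_true(is.na(agg0$driver[1, 1]))

  # driver mode by count: fire x5 vs forestry x3
  lm2 <- matrix(0, 4, 4); lm2[1:8] <- 1
  dv2 <- matrix(NA_character_, 4, 4)
  dv2[1:5] <- "fire"; dv2[6:8] <- "forestry"
  agg2 <- aggregate_forest_maps(lm2, cv, dv2, 4)
  expect_equal(agg2$driver[1, 1], "fire")

  # tie broken by fixed class order (cCRO before fire)
  dv3 <- dv2; dv3[1:4] <- "cCRO"; dv3[5:8] <- "fire"
  expect_equal(aggregate_forest_maps(lm2, cv, dv3, 4)$driver[1, 1], "cCRO")

  # partial cover scales the loss percentage
  cv2 <- matrix(0.5, 4, 4)
  expect_equal(aggregate_forest_maps(lm_, cv2, dv, 4)$loss_pct[1, 1], 25)

  expect_error(aggregate_forest_maps(lm_, cv, dv, 3), "tile")
})

fake_decomp <- function(breaks_df, start_year = 2003, n_years = 18) {
  structure(list(breakpoints = breaks_df,
                 series = list(start_year = start_year,
                               n_years = n_years, period = 36L)),
            class = "lst_decomp")
}

break_row <- function(component, year, lo, hi) {
  data.frame(component = component, step = (year - 2003) * 36 + 1,
             year = year, ci_lo_step = (lo - 2003) * 36 + 1,
             ci_hi_step = (hi - 2003) * 36 + 36, ci_lo_year = lo,
             ci_hi_year = hi, magnitude = 1)
}

test_that("loss events match breaks inside the CI within two years", {
  dec <- fake_decomp(rbind(break_row("trend", 2005, 2004, 2006),
                           break_row("seasonal", 2006, 2005, 2007)))
  m <- match_loss_to_breaks(list(loss_year = 2005), dec)
  expect_equal(nrow(m), 2L)  # both trend 2005 and seasonal 2006 match

  # loss outside the CI: no match
  dec2 <- fake_decomp(break_row("trend", 2014, 2013, 2015))
  expect_equal(nrow(match_loss_to_breaks(list(loss_year = 2010), dec2)), 0L)

  # boundary: inside CI with a gap of exactly two years still matches
  dec3 <- fake_decomp(break_row("trend", 2010, 2007, 2011))
  expect_equal(nrow(match_loss_to_breaks(list(loss_year = 2008), dec3)), 1L)

  # inside CI but more than two years away: rejected
  dec4 <- fake_decomp(break_row("trend", 2011, 2007, 2012))
  expect_equal(nrow(match_loss_to_breaks(list(loss_year = 2008), dec4)), 0L)
})

test_that("the loss window unites the loss year and matched break years", {
  m <- rbind(break_row("trend", 2005, 2004, 2006),
             break_row("seasonal", 2006, 2005, 2007))
  w <- loss_window(list(loss_year = 2005), m)
  expect_equal(c(w$start, w$end), c(2005, 2006))

  w2 <- loss_window(list(loss_year = 2009),
                    break_row("trend", 2009, 2008, 2010))
  expect_equal(c(w2$start, w2$end), c(2009, 2009))

  w3 <- loss_window(list(loss_year = 2010),
                    break_row("trend", 2008, 2007, 2009))
  expect_equal(c(w3$start, w3$end), c(2008, 2010))

  expect_error(loss_window(list(loss_year = 2005), m[0, ]), "matched")
})

test_that("the study period runs two years ahead of the window to the next break", {
  # worked case: window 2005-2006, next break CI starts 2015, series to 2020
  bks <- rbind(break_row("trend", 2005, 2004, 2006),
               break_row("trend", 2016, 2015, 2017))
  p <- study_period(list(start = 2005, end = 2006), bks, 2003, 2020)
  expect_true(p$usable)
  expect_equal(c(p$start, p$end), c(2003, 2014))

  # no later break: period extends to the series end
  p2 <- study_period(list(start = 2009, end = 2009),
                     break_row("trend", 2009, 2008, 2010), 2003, 2020)
  expect_equal(c(p2$start, p2$end), c(2007, 2020))

  # immediate next break: empty post-loss span flagged unusable
  bks3 <- rbind(break_row("trend", 2005, 2004, 2006),
                break_row("seasonal", 2008, 2007, 2009))
  p3 <- study_period(list(start = 2005, end = 2006), bks3, 2003, 2020)
  expect_false(p3$usable)

  expect_error(study_period(list(start = 2004, end = 2004), bks, 2003,
                            2020), "before the series")
})

test_that("background selection enforces the annulus and stability rules", {
  target <- list(x = 0, y = 0, elevation = 300, loss_pct = 40)
  cand <- data.frame(
    x = c(30000, 10000, 30000, 30000, 60000, 25000, 50000),
    y = 0,
    elevation = c(350, 300, 300, 450, 300, 300, 300),
    landcover = c("forest", "forest", "cropland", "forest", "forest",
                  "forest", "forest"),
    change_pct = c(1, 0, 0, 0, 0, 1.9, 2.5),
    row = 1:7, col = 1:7)
  sel <- select_background(target, cand, min_valid_frac = 0)
  # candidate 1: all rules pass; 2: inside inner radius; 3: non-forest;
  # 4: elevation 150 m; 5: outside; 6: boundary distances inclusive;
  # 7: change over the 2% ceiling
  expect_setequal(sel$background$row, c(1, 6))
  expect_equal(sel$n_annulus, 5L)

  # change threshold uses min(2, P): P = 1.5 tightens the ceiling
  t2 <- list(x = 0, y = 0, elevation = 300, loss_pct = 1.5)
  sel2 <- select_background(t2, cand, min_valid_frac = 0)
  expect_setequal(sel2$background$row, 1)  # row 6 (1.9%) over min(2, 1.5)
  expect_true(all(sel2$background$change_pct < 1.5))

  # 5% retention rule: 12 valid of 400 candidates -> excluded
  many <- data.frame(
    x = 30000, y = 0, elevation = c(rep(300, 12), rep(600, 388)),
    landcover = "forest", change_pct = 0, row = 1, col = seq_len(400))
  sel3 <- select_background(target, many)
  expect_false(sel3$accepted)
  expect_match(sel3$reason, "5%")

  # empty annulus
  sel4 <- select_background(target, cand[cand$x == 10000, , drop = FALSE])
  expect_false(sel4$accepted)
  expect_match(sel4$reason, "empty")
})

test_that("selection is idempotent and distances stay inside the annulus", {
  sc <- make_scene(scene_config(nrow = 24, ncol = 24, pixel_size = 5000,
                                start_year = 2003, end_year = 2012,
                                n_events = 3,
                                loss_year_range = c(2006, 2009), seed = 11,
                                min_valid_candidates = 10L))
  px <- scene_pixels(sc)
  for (i in seq_len(nrow(sc$truth))) {
    ev <- sc$truth[i, ]
    tgt <- list(x = ev$x, y = ev$y,
                elevation = sc$elevation[ev$row, ev$col],
                loss_pct = ev$loss_pct)
    sel <- select_background(tgt, px)
    expect_true(all(sel$background$distance >= 25000 &
                      sel$background$distance <= 50000))
    sel2 <- select_background(tgt, sel$background)
    expect_setequal(paste(sel2$background$row, sel2$background$col),
                    paste(sel$background$row, sel$background$col))
    # other event pixels are never accepted as background
    others <- sc$truth[-i, c("row", "col")]
    expect_false(any(paste(others$row, others$col) %in%
                       paste(sel$background$row, sel$background$col)))
  }
})
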