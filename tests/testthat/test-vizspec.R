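test_that("wave plot density integrates to ~1 with exponentiated ticks", {
  set.seed(51)
  for (mu in c(-0.4, 0, 0.3)) {
    x <- exp(rnorm(1500, mu, 0.25))
    spec <- wave_plot_spec(x, area_id = "w")
    expect_gte(trapezoid(spec$log_grid, spec$density), 0.98)
    expect_lte(trapezoid(spec$log_grid, spec$density), 1.02)
    expect_true(all(spec$density >= 0))
    # tick label equals exp(position) at formatting precision
    expect_equal(as.numeric(spec$ticks$label), exp(spec$ticks$position),
                 tolerance = 0.005)
    expect_identical(spec$ticks$label,
                     as.character(signif(exp(spec$ticks$position), 3)))
  }
  expect_error(wave_plot_spec(exp(rnorm(10))), "50")
})

test_that("wave plot peaks at the mode and matches the normal pdf oracle", {
  set.seed(52)
  z <- rnorm(5000, 0, 0.25)
  sym <- exp(c(z, -z))  # exactly symmetric in log space around 0
  spec_sym <- wave_plot_spec(sym, grid_size = 512)
  step <- diff(spec_sym$log_grid[1:2])
  expect_lt(abs(spec_sym$log_grid[which.max(spec_sym$density)]), 2 * step)

  x <- exp(rnorm(10000, 0, 0.25))
  spec <- wave_plot_spec(x, grid_size = 512)
  # closed-form N(0, 0.25^2) density at 0: 1/(0.25 sqrt(2 pi))
  at0 <- spec$density[which.min(abs(spec$log_grid))]
  expect_equal(at0, 1 / (0.25 * sqrt(2 * pi)), tolerance = 0.1)
  # overlay carries the summary quantities
  expect_equal(spec$point, unname(quantile(x, 0.5)))
  expect_equal(spec$ci80, unname(quantile(x, c(0.1, 0.9))))
})

test_that("V-plot folds the PPD symmetrically about the average", {
  s <- make_summaries(c(0.8, 1.2, 1), c(0.2, 0.8, 0.5))
  vp <- v_plot_spec(s)
  expect_equal(vp$y, c(0.8, 0.8, 0.5))
  expect_equal(vp$x, s$point)

  # reciprocal draws mirror x about 1 (log axis) and leave y unchanged
  set.seed(53)
  mat <- matrix(exp(rnorm(501 * 3, c(-0.5, 0.2, 0.6), 0.3)), 501, 3,
                dimnames = list(NULL, c("a", "b", "c")))
  v1 <- v_plot_spec(summarize_all(mat))
  v2 <- v_plot_spec(summarize_all(1 / mat))
  expect_equal(log(v2$x), -log(v1$x))
  expect_equal(v2$y, v1$y)

  # rank correlation between |log x| and y equals a brute-force loop
  su <- summarize_all(mat)
  r1 <- cor(abs(log(v1$x)), v1$y, method = "spearman")
  r2 <- cor(abs(log(su$point)), pmax(su$ppd, 1 - su$ppd),
            method = "spearman")
  expect_equal(r1, r2)

  bad <- make_summaries(1, 0.5, ids = "zz")
  st <- apply_transparency("#FF0000", 0.5, area_id = "other")
  expect_error(v_plot_spec(bad, st), "align")
})

test_that("estimate colors anchor the national average at pale yellow", {
  expect_equal(estimate_color(1), "#FFFFBF")
  # regardless of (asymmetric) breakpoints
  expect_equal(estimate_color(1, breakpoints = c(0.5, 4)), "#FFFFBF")
  # clamping below the low breakpoint
  expect_equal(estimate_color(0.25), estimate_color(0.5))
  expect_equal(estimate_color(8), estimate_color(2))
  # quarter point: t = 0.25 -> midway between anchors 3 and 4 of 11
  anchors <- c("#313695", "#4575B4", "#74ADD1", "#ABD9E9", "#E0F3F8",
               "#FFFFBF", "#FEE090", "#FDAE61", "#F46D43", "#D73027",
               "#A50026")
  want <- round((col2rgb(anchors[3]) + col2rgb(anchors[4])) / 2)
  got <- col2rgb(estimate_color(sqrt(0.5)))  # log e = 0.5 log lo -> t = 0.25
  expect_true(all(abs(got - want) <= 1))
  expect_error(estimate_color(-1), "positive")
})

test_that("transparency fades uncertain areas toward the average yellow", {
  st_mid <- apply_transparency("#D73027", 0.5)
  expect_equal(st_mid$alpha, 0.1)            # maximal fade at ppd = 0.5
  expect_equal(st_mid$rendered, .blend_oracle("#D73027", 0.1))
  st_sure <- apply_transparency("#D73027", 1)
  expect_equal(st_sure$alpha, 1)
  expect_equal(st_sure$rendered, "#D73027")  # fill unchanged
  # piecewise-linear middle segment: c = 0.3 -> 0.1 + 0.9 * 0.1/0.4
  expect_equal(apply_transparency("#D73027", 0.65)$alpha, 0.325)
  # monotone in |ppd - 0.5|
  p <- seq(0, 1, by = 0.01)
  a <- apply_transparency("#D73027", p)$alpha
  expect_true(all(diff(a[p >= 0.5]) >= 0))
  expect_equal(a, rev(a))
  # disabled toggle
  off <- apply_transparency("#D73027", p, enabled = FALSE)
  expect_true(all(off$alpha == 1))
  expect_error(apply_transparency("#D73027", 0.5, mapping = c(0.6, 0.2, 0.1)),
               "mapping")
})

test_that("area styles differ with/without transparency only where faded", {
  s <- make_summaries(c(0.6, 1.5, 1.02, 0.98), c(0.01, 0.99, 0.55, 0.4))
  on <- area_styles(s)
  off <- area_styles(s, enabled = FALSE)
  expect_identical(on$fill, off$fill)
  differs <- on$rendered != off$rendered
  expect_identical(differs, on$alpha < 1)
})

test_that("grouped overviews conserve counts and percentages", {
  set.seed(54)
  point <- exp(rnorm(30, 0, 0.4))
  s <- make_summaries(point, runif(30))
  groups <- setNames(rep(c("city", "regional", "remote"), each = 10),
                     s$area_id)
  ov_pct <- overview_spec(s, groups, "percentage")
  expect_equal(unname(rowSums(ov_pct$values)), rep(100, 3), tolerance = 1e-4)
  ov_cnt <- overview_spec(s, groups, "count")
  expect_equal(unname(rowSums(ov_cnt$values)), rep(10, 3))
  # boxplot mode: five-number summaries match a sorting oracle
  ov_box <- overview_spec(s, groups, "boxplot")
  for (g in unique(groups)) {
    expect_equal(unname(ov_box$values[g, ]),
                 fivenum(point[groups[s$area_id] == g]))
  }
  # all estimates in one class -> 100% in that class
  s_one <- make_summaries(rep(1.01, 4), rep(0.5, 4))
  ov_one <- overview_spec(s_one, setNames(rep("g", 4), s_one$area_id))
  expect_equal(max(ov_one$values), 100)
  expect_equal(sum(ov_one$values > 0), 1)
  expect_error(overview_spec(s, groups[-1]), "unassigned")
})

test_that("specs serialize to valid JSON", {
  s <- make_summaries(c(0.8, 1.3), c(0.1, 0.9))
  js <- spec_to_json(v_plot_spec(s))
  back <- jsonlite::fromJSON(js)
  expect_equal(back$x, s$point)
})
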