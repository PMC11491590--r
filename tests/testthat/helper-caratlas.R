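# shared fixtures, all built in code

# wrap a draws matrix as a posterior_draws object (for summary/diagnostic
# tests that do not need a fitted chain)
fake_draws <- function(mat, area_ids = colnames(mat)) {
  if (is.null(area_ids)) {
    area_ids <- paste0("a", seq_len(ncol(mat)))
    colnames(mat) <- area_ids
  }
  structure(list(area_ids = area_ids, draws = mat,
                 hyper = data.frame(rho = numeric(0), sigma2 = numeric(0)),
                 meta = list(model = "incidence", accept = list(),
                             warnings = character(0))),
            class = "posterior_draws")
}

# FeatureCollection of unit squares with lower-left corners at `origins`
# (list of c(x, y)) and the given ids
square_fc <- function(origins, ids) {
  features <- lapply(seq_along(ids), function(k) {
    x0 <- origins[[k]][1]; y0 <- origins[[k]][2]
    ring <- list(c(x0, y0), c(x0 + 1, y0), c(x0 + 1, y0 + 1),
                 c(x0, y0 + 1), c(x0, y0))
    list(type = "Feature", properties = list(area_id = ids[k]),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  list(type = "FeatureCollection", features = features)
}

# summaries with prescribed point estimates and PPDs
make_summaries <- function(point, p, ids = paste0("a", seq_along(point))) {
  mats <- vapply(seq_along(point), function(i) c(point[i], point[i]),
                 numeric(2))
  out <- data.frame(area_id = ids, point = point,
                    ci60_lo = point * 0.9, ci60_hi = point * 1.1,
                    ci80_lo = point * 0.8, ci80_hi = point * 1.2,
                    ppd = p, v_conf = pmax(p, 1 - p),
                    category = classify_difference(p),
                    stringsAsFactors = FALSE)
  structure(out, class = c("area_summary", "data.frame"))
}

trapezoid <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# independent alpha-compositing arithmetic over an opaque base
.blend_oracle <- function(fill, alpha, base = "#FFFFBF") {
  f <- col2rgb(fill)
  b <- col2rgb(base)
  m <- f * alpha + b * (1 - alpha)
  rgb(m[1, ], m[2, ], m[3, ], maxColorValue = 255)
}
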