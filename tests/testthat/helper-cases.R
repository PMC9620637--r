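# Shared fixtures, built in code.

# Collinear keypoints at given 1-D millimetre positions along a line through
# `origin` at `angle_deg`, converted to pixels at `mpp` mm/px.
collinear_points <- function(positions_mm, mpp = 1, origin = c(30, 30),
                             angle_deg = 0) {
  th <- angle_deg * pi / 180
  u <- c(cos(th), sin(th))
  t(vapply(positions_mm, function(p) origin + p / mpp * u, numeric(2)))
}

# A small measurement set with every rim comfortably eligible.
eligible_measurements <- function(max_d = 12, rims = 10, septum = 40) {
  assemble_measurements(
    c(defect_diameter_pssax_mm = max_d, rim_wall_mm = rims),
    c(defect_diameter_sxlax_mm = max_d - 1, rim_svc_mm = rims,
      rim_ivc_mm = rims),
    c(defect_diameter_a4c_mm = max_d - 2, rim_roof_mm = rims,
      rim_mitral_mm = rims, septum_length_mm = septum))
}

# Independent recursive rule evaluator used as the brute-force oracle.
oracle_eval <- function(node, values) {
  if (!is.null(node$measure)) {
    th <- if (is.character(node$threshold)) values[[node$threshold]]
          else node$threshold
    switch(node$cmp,
           "<" = values[[node$measure]] < th,
           "<=" = values[[node$measure]] <= th,
           ">" = values[[node$measure]] > th,
           ">=" = values[[node$measure]] >= th,
           "=" = , "==" = values[[node$measure]] == th)
  } else {
    vals <- vapply(node$children, oracle_eval, logical(1), values = values)
    switch(node$op, AND = all(vals), OR = any(vals), NOT = !vals[1])
  }
}

# Random Boolean tree with exactly `n_leaves` leaves over measurements m1..mk.
random_tree <- function(n_leaves, rng) {
  leaf_id <- 0
  build <- function(n) {
    if (n == 1) {
      leaf_id <<- leaf_id + 1
      list(measure = paste0("m", leaf_id),
           cmp = sample(c("<", "<=", ">", ">=", "="), 1),
           threshold = round(runif(1, 1, 9), 1))
    } else if (runif(1) < 0.2) {
      list(op = "NOT", children = list(build(n)))
    } else {
      k <- sample(seq_len(n - 1), 1)
      list(op = sample(c("AND", "OR"), 1),
           children = list(build(k), build(n - k)))
    }
  }
  build(n_leaves)
}

small_view_case <- function(seed, image_size = 64, class_mix = 0.6) {
  generate_cases(1, rng_seed = seed, class_mix = class_mix,
                 image_size = image_size)[[1]]
}
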