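# Boolean rule engine over millimetre measurements.
#
# A rule set is an expression tree: internal nodes are AND / OR / NOT, leaves
# compare a named measurement against a threshold. A leaf threshold may also
# name another measurement (the shipped default compares the septum length
# against the suggested occluder size, which decide() injects as the derived
# measurement "suggested_size_mm"). Evaluation returns the truth value plus a
# per-leaf trace - the interpretability surface a clinician can audit.

.cmp_funs <- list(
  "<"  = `<`, "<=" = `<=`, ">"  = `>`, ">=" = `>=`, "==" = `==`, "=" = `==`)

.is_leaf <- function(node) !is.null(node$measure)

.validate_node <- function(node) {
  if (!is.list(node)) stop("malformed rule node", call. = FALSE)
  if (.is_leaf(node)) {
    if (is.null(node$cmp) || !node$cmp %in% names(.cmp_funs))
      stop("leaf comparator must be one of <, <=, >, >=, =", call. = FALSE)
    if (is.null(node$threshold))
      stop("leaf needs a threshold", call. = FALSE)
    if (!(is.numeric(node$threshold) || is.character(node$threshold)))
      stop("threshold must be a number or a measurement name", call. = FALSE)
  } else {
    if (is.null(node$op) || !node$op %in% c("AND", "OR", "NOT"))
      stop("internal node op must be AND, OR or NOT", call. = FALSE)
    n <- length(node$children)
    if (node$op == "NOT" && n != 1L)
      stop("NOT takes exactly one child", call. = FALSE)
    if (node$op != "NOT" && n < 1L)
      stop(node$op, " needs at least one child", call. = FALSE)
    lapply(node$children, .validate_node)
  }
  invisible(TRUE)
}

#' Parse a rule-set configuration into a RuleSet
#'
#' Accepts a nested list (e.g. from YAML/JSON) of `{op, children}` internal
#' nodes and `{measure, cmp, threshold}` leaves, a YAML/JSON file path, or a
#' YAML string.
#'
#' @param config Nested list, or path to a YAML/JSON file, or YAML text.
#' @return A `rule_set` object.
#' @export
parse_ruleset <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (file.exists(config)) yaml::read_yaml(config)
              else yaml::yaml.load(config)
  }
  if (is.null(config) || !is.list(config) || length(config) == 0L)
    stop("empty or malformed rule-set config", call. = FALSE)
  .validate_node(config)
  structure(list(tree = config), class = "rule_set")
}

#' Serialize a RuleSet back to its configuration list
#'
#' `parse_ruleset(serialize_ruleset(r))` is the identity.
#'
#' @param rules A `rule_set`.
#' @return The nested configuration list.
#' @export
serialize_ruleset <- function(rules) rules$tree

#' Count the leaves of a rule set
#' @param rules A `rule_set`.
#' @return Integer number of conditional-statement leaves.
#' @export
rule_leaf_count <- function(rules) {
  n_leaves <- function(node) {
    if (.is_leaf(node)) 1L
    else sum(vapply(node$children, n_leaves, integer(1)))
  }
  n_leaves(rules$tree)
}

#' Default transcatheter-eligibility rule set
#'
#' All five rims (aortic wall, SVC, IVC, atrial roof, mitral annulus) must be
#' at least `rim_min_mm`, and the atrial septum must be longer than the
#' suggested occluder size so the device fits within the septum. The 5 mm rim
#' default is the conventional device-rim criterion; both it and the tree are
#' fully configurable for other occluder types.
#'
#' @param rim_min_mm Minimum acceptable rim length in mm (default 5).
#' @return A `rule_set` with six leaves.
#' @export
default_ruleset <- function(rim_min_mm = 5) {
  leaf <- function(measure, cmp, threshold)
    list(measure = measure, cmp = cmp, threshold = threshold)
  parse_ruleset(list(op = "AND", children = list(
    leaf("rim_wall_mm",   ">=", rim_min_mm),
    leaf("rim_svc_mm",    ">=", rim_min_mm),
    leaf("rim_ivc_mm",    ">=", rim_min_mm),
    leaf("rim_roof_mm",   ">=", rim_min_mm),
    leaf("rim_mitral_mm", ">=", rim_min_mm),
    leaf("septum_length_mm", ">", "suggested_size_mm"))))
}

#' Default occluder catalogue
#'
#' Waist diameters available for the modelled septal occluder device family
#' (integer millimetres 8 to 32) and the sizing margin added to the maximum
#' measured defect diameter (4 mm).
#'
#' @param sizes_mm Strictly increasing integer sizes (default `8:32`).
#' @param margin_mm Sizing margin in mm (default 4).
#' @return An `occluder_catalogue` object.
#' @export
occluder_catalogue <- function(sizes_mm = 8:32, margin_mm = 4) {
  if (length(sizes_mm) == 0L || is.unsorted(sizes_mm, strictly = TRUE))
    stop("catalogue sizes must be non-empty and strictly increasing",
         call. = FALSE)
  structure(list(sizes_mm = as.integer(sizes_mm), margin_mm = margin_mm),
            class = "occluder_catalogue")
}

#' Evaluate a rule set against a measurement set
#'
#' @param rules A `rule_set`.
#' @param m A `measurement_set` (or named list/vector of measurements).
#' @return List with `value` (logical) and `trace`: a data frame with one row
#'   per leaf (measurement name, comparator, threshold, measured value, truth
#'   value).
#' @export
evaluate_rules <- function(rules, m) {
  if (!inherits(rules, "rule_set")) stop("rules must be a rule_set",
                                         call. = FALSE)
  mv <- unlist(m)
  trace <- list()
  resolve <- function(th) {
    if (is.character(th)) {
      if (!th %in% names(mv))
        stop("unknown measurement name '", th, "' in rule threshold",
             call. = FALSE)
      mv[[th]]
    } else th
  }
  ev <- function(node) {
    if (.is_leaf(node)) {
      if (!node$measure %in% names(mv))
        stop("unknown measurement name '", node$measure, "' in rule",
             call. = FALSE)
      val <- mv[[node$measure]]
      th <- resolve(node$threshold)
      res <- if (is.na(val) || is.na(th)) FALSE
             else .cmp_funs[[node$cmp]](val, th)
      trace[[length(trace) + 1L]] <<- data.frame(
        measure = node$measure, cmp = node$cmp,
        threshold = if (is.character(node$threshold)) node$threshold
                    else format(node$threshold),
        threshold_mm = as.numeric(th), value_mm = as.numeric(val),
        satisfied = res, stringsAsFactors = FALSE)
      res
    } else {
      vals <- vapply(node$children, ev, logical(1))
      switch(node$op, AND = all(vals), OR = any(vals), NOT = !vals[1])
    }
  }
  value <- ev(rules$tree)
  list(value = value, trace = do.call(rbind, trace))
}

#' Suggest an occluder size for a measurement set
#'
#' The sizing rule: target size = maximum defect diameter over the three
#' views plus the catalogue margin (default 4 mm); the suggestion is the
#' smallest catalogue size at least as large as the target.
#'
#' @param m A `measurement_set` (needs `max_defect_diameter_mm`).
#' @param cat An `occluder_catalogue`.
#' @return Integer size in mm. Throws a condition of class
#'   `dks_size_unavailable` when the target exceeds the largest catalogue
#'   size (callers fall back to surgical closure).
#' @export
suggest_size <- function(m, cat = occluder_catalogue()) {
  maxd <- unlist(m)[["max_defect_diameter_mm"]]
  if (is.na(maxd) || maxd < 0)
    stop("max_defect_diameter_mm must be non-negative", call. = FALSE)
  target <- maxd + cat$margin_mm
  ok <- cat$sizes_mm[cat$sizes_mm >= target]
  if (length(ok) == 0L)
    stop(errorCondition(
      sprintf("no catalogue size >= %.1f mm (target exceeds %d mm)",
              target, max(cat$sizes_mm)),
      class = c("dks_size_unavailable", "error")))
  ok[1]
}

#' Decide the closure plan for a measurement set
#'
#' Transcatheter closure is suggested iff the rule set is satisfied and a
#' catalogue size is available for the defect; otherwise surgical closure.
#' The rule trace is always populated, including the derived
#' `suggested_size_mm` operand, so every decision can be audited leaf by
#' leaf.
#'
#' @param m A `measurement_set`.
#' @param rules A `rule_set` (default [default_ruleset()]).
#' @param cat An `occluder_catalogue` (default [occluder_catalogue()]).
#' @return A `decision_result`: list with `plan`, `suggested_size_mm`
#'   (integer or `NA`), and `rule_trace`.
#' @export
decide <- function(m, rules = default_ruleset(), cat = occluder_catalogue()) {
  size <- tryCatch(suggest_size(m, cat),
                   dks_size_unavailable = function(e) NA_integer_)
  m_aug <- c(unlist(m), suggested_size_mm = as.numeric(size))
  ev <- evaluate_rules(rules, m_aug)
  plan <- if (isTRUE(ev$value) && !is.na(size)) "transcatheter" else "surgical"
  structure(list(
    plan = plan,
    suggested_size_mm = if (plan == "transcatheter") as.integer(size)
                        else NA_integer_,
    rule_trace = ev$trace), class = "decision_result")
}

#' @export
print.decision_result <- function(x, ...) {
  cat(sprintf("<decision: %s%s>\n", x$plan,
              if (!is.na(x$suggested_size_mm))
                sprintf(", occluder %d mm", x$suggested_size_mm) else ""))
  print(x$rule_trace, row.names = FALSE)
  invisible(x)
}
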