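#' Matching specification
#'
#' Variables matched exactly and caliper half-widths for the continuous
#' covariates. Defaults: exact match on sex and Kellgren-Lawrence grade;
#' body height within 3 cm, BMI within 5 kg/m2, WOMAC pain (0-20 scale)
#' within 5 points.
#'
#' @param exact_vars Character vector of columns matched exactly.
#' @param calipers Named numeric vector of maximal absolute differences.
#' @return A list of class `match_spec`.
#' @export
match_spec <- function(exact_vars = c("sex", "klg"),
                       calipers = c(height_cm = 3, bmi_kg_m2 = 5,
                                    womac_pain = 5)) {
  if (length(calipers) && (is.null(names(calipers)) || any(names(calipers) == "")))
    abort_menisq("calipers must be a named numeric vector", "menisq_invalid_input")
  if (any(calipers <= 0))
    abort_menisq("calipers must be positive", "menisq_invalid_input")
  structure(list(exact_vars = exact_vars, calipers = calipers),
            class = "match_spec")
}

# Eligibility and caliper-normalized distance for one case/control pair.
pair_eligible <- function(case, control, spec) {
  for (v in spec$exact_vars) {
    a <- case[[v]]; b <- control[[v]]
    if (is.null(a) || is.null(b) || is.na(a) || is.na(b) || a != b) return(NA_real_)
  }
  d <- 0
  for (v in names(spec$calipers)) {
    a <- case[[v]]; b <- control[[v]]
    if (is.null(a) || is.null(b) || is.na(a) || is.na(b)) return(NA_real_)
    delta <- abs(as.numeric(a) - as.numeric(b))
    if (delta > spec$calipers[[v]]) return(NA_real_)
    d <- d + delta / spec$calipers[[v]]
  }
  d
}

# m x n matrix of caliper-normalized distances, NA where ineligible.
match_distance_matrix <- function(cases, controls, spec) {
  m <- nrow(cases); n <- nrow(controls)
  D <- matrix(NA_real_, m, n)
  for (i in seq_len(m))
    for (j in seq_len(n))
      D[i, j] <- pair_eligible(cases[i, , drop = FALSE],
                               controls[j, , drop = FALSE], spec)
  D
}

#' 1:1 caliper-constrained case-control matching
#'
#' Pairs each case with at most one control such that all exact variables
#' agree and all caliper constraints hold. `method = "optimal"` (default)
#' solves a weighted bipartite matching that first maximises the number of
#' pairs and, among maximum-cardinality matchings, minimises the total
#' caliper-normalized distance (sum over pairs of `|diff| / caliper`);
#' `method = "greedy"` walks cases in input order and takes the nearest
#' unused eligible control (provided for sensitivity analysis). Both are
#' deterministic given the input order. Unmatched cases are reported via
#' the `unmatched_cases` attribute, not raised.
#'
#' @param cases,controls data.frames with an id column (`knee_id` if
#'   present, else row index) and the covariates named in `spec`.
#' @param spec A [match_spec()].
#' @param method `"optimal"` or `"greedy"`.
#' @return data.frame with `case_id`, `control_id`, `distance`; attributes
#'   `unmatched_cases` (ids) and `total_distance`.
#' @export
match_pairs <- function(cases, controls, spec = match_spec(),
                        method = c("optimal", "greedy")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(cases), is.data.frame(controls),
            inherits(spec, "match_spec"))
  case_ids <- if ("knee_id" %in% names(cases)) cases$knee_id else seq_len(nrow(cases))
  ctrl_ids <- if ("knee_id" %in% names(controls)) controls$knee_id else seq_len(nrow(controls))
  D <- match_distance_matrix(cases, controls, spec)
  assign_ctrl <- rep(NA_integer_, nrow(cases))

  if (method == "greedy") {
    used <- logical(nrow(controls))
    for (i in seq_len(nrow(cases))) {
      cand <- which(!is.na(D[i, ]) & !used)
      if (length(cand)) {
        j <- cand[which.min(D[i, cand])]
        assign_ctrl[i] <- j
        used[j] <- TRUE
      }
    }
  } else if (any(!is.na(D))) {
    # Weighted bipartite matching: edge weight BIG - distance makes maximum
    # total weight equivalent to maximum cardinality with minimum total
    # distance (BIG exceeds any achievable distance sum).
    edges <- which(!is.na(D), arr.ind = TRUE)
    big <- (length(spec$calipers) + 1) * (min(nrow(D), ncol(D)) + 1)
    m <- nrow(cases)
    g <- igraph::make_empty_graph(n = m + nrow(controls), directed = FALSE)
    igraph::V(g)$type <- c(rep(FALSE, m), rep(TRUE, nrow(controls)))
    g <- igraph::add_edges(g, rbind(edges[, 1L], m + edges[, 2L]))
    igraph::E(g)$weight <- big - D[edges]
    mm <- igraph::max_bipartite_match(g)
    matched <- mm$matching[seq_len(m)]
    assign_ctrl <- ifelse(is.na(matched), NA_integer_, as.integer(matched) - m)
  }

  paired <- which(!is.na(assign_ctrl))
  out <- data.frame(
    case_id = case_ids[paired],
    control_id = ctrl_ids[assign_ctrl[paired]],
    distance = D[cbind(paired, assign_ctrl[paired])],
    stringsAsFactors = FALSE)
  attr(out, "unmatched_cases") <- case_ids[setdiff(seq_len(nrow(cases)), paired)]
  attr(out, "total_distance") <- sum(out$distance)
  out
}
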