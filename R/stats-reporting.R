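#' Replicate-structured value table
#'
#' Holds one measured quantity (e.g. fitted Rb, alpha, Cm or a
#' colocalization coefficient) for individual electrodes nested in
#' independent experiments, per condition -- the structure behind
#' per-experiment averaging and the replicate-aware statistics.
#'
#' @param data data.frame with columns `experiment_id`, `condition`,
#'   `electrode_id`, `value`.
#' @param value_kind What the value measures (e.g. `"Rb"`).
#' @param unit Unit string (e.g. `"Ohm cm^2"`).
#' @return An object of class `experiment_table` (a data.frame).
#' @export
experiment_table <- function(data, value_kind = "value", unit = "") {
  need <- c("experiment_id", "condition", "electrode_id", "value")
  if (!all(need %in% names(data))) {
    stop("missing columns: ",
         paste(setdiff(need, names(data)), collapse = ", "), call. = FALSE)
  }
  if (nrow(data) == 0) stop("empty table", call. = FALSE)
  if (any(!is.finite(data$value))) {
    stop("values must be finite", call. = FALSE)
  }
  structure(as.data.frame(data), value_kind = value_kind, unit = unit,
            class = c("experiment_table", "data.frame"))
}

#' Average electrodes within each experiment
#'
#' Each (experiment, condition) group of electrodes -- typically N = 4
#' wells of one array -- is reduced to its arithmetic mean; these
#' per-experiment means are the units all downstream statistics operate
#' on.
#'
#' @param table An [experiment_table()].
#' @return data.frame with `experiment_id`, `condition`, `n_electrodes`,
#'   `mean_value`.
#' @export
aggregate_electrodes <- function(table) {
  stopifnot(inherits(table, "experiment_table"))
  key <- interaction(table$experiment_id, table$condition, drop = TRUE)
  out <- do.call(rbind, lapply(split(table, key), function(g) {
    data.frame(experiment_id = g$experiment_id[1],
               condition = g$condition[1],
               n_electrodes = nrow(g),
               mean_value = mean(g$value),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$condition, out$experiment_id), , drop = FALSE]
}

#' One-way fixed-effects ANOVA, reported as "A(F;P)"
#'
#' Classical one-way ANOVA across two or more groups of per-experiment
#' means: F = MS_between / MS_within with P from the F distribution.
#' When the within-group variance is exactly zero while group means
#' differ, F is reported as `Inf` with `p_below_machine = TRUE`.
#'
#' @param groups Named (or unnamed) list of >= 2 numeric vectors, each
#'   of length >= 2.
#' @return List with `f`, `p`, `df_between`, `df_within`,
#'   `p_below_machine` and the rendered `label` (see [format_afp()]).
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("'groups' must be a list of at least two groups", call. = FALSE)
  }
  if (any(vapply(groups, length, 1L) < 2)) {
    stop("each group needs at least two values", call. = FALSE)
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  means <- vapply(groups, mean, 1)
  zero_within <- all(vapply(groups, function(x) all(x == x[1]), TRUE))
  df_b <- length(groups) - 1L
  df_w <- length(y) - length(groups)
  p_below <- FALSE
  if (zero_within) {
    # exact-arithmetic degenerate cases, not reachable through lm noise
    if (all(means == means[1])) {
      stop("degenerate data: zero variance everywhere", call. = FALSE)
    }
    f <- Inf; p <- 0; p_below <- TRUE
  } else {
    tab <- stats::anova(stats::lm(y ~ g))
    f <- tab[["F value"]][1]
    p <- tab[["Pr(>F)"]][1]
  }
  list(f = f, p = p, df_between = df_b, df_within = df_w,
       p_below_machine = p_below, label = format_afp(f, p))
}

#' Two-tailed Student's t-test
#'
#' Paired (the convention for pre/post comparisons within experiments)
#' or unpaired with pooled variance (the classical Student form, the
#' convention for qPCR group comparisons); Welch's correction is
#' available for the unpaired case but is not the default. A zero
#' variance of the paired differences (or of both samples) has no
#' finite t; the result is then flagged `degenerate` with `t` and `p`
#' set to `NA`.
#'
#' @param a,b Numeric vectors (paired: equal length >= 2).
#' @param mode `"paired"` or `"unpaired"`.
#' @param welch Use Welch's unequal-variance form (unpaired only)?
#' @return List with `t`, `p`, `df`, `mode`, `degenerate`.
#' @export
ttest <- function(a, b, mode = c("paired", "unpaired"), welch = FALSE) {
  mode <- match.arg(mode)
  if (mode == "paired" && length(a) != length(b)) {
    stop("paired test requires equal lengths", call. = FALSE)
  }
  if (length(a) < 2 || length(b) < 2) {
    stop("each sample needs at least two values", call. = FALSE)
  }
  res <- tryCatch(
    stats::t.test(a, b, paired = mode == "paired",
                  var.equal = mode == "unpaired" && !welch,
                  alternative = "two.sided"),
    error = function(e) NULL)
  if (is.null(res) || !is.finite(res$statistic)) {
    return(list(t = NA_real_, p = NA_real_, df = NA_real_, mode = mode,
                degenerate = TRUE))
  }
  list(t = unname(res$statistic), p = res$p.value,
       df = unname(res$parameter), mode = mode, degenerate = FALSE)
}

#' Render and parse the "A(F;P)" ANOVA annotation
#'
#' @param f F statistic.
#' @param p P value.
#' @param digits Significant digits (default 3). P values below 1e-4
#'   are rendered in scientific notation.
#' @return `format_afp`: a string like `"A(4.56;0.0123)"`.
#' @export
format_afp <- function(f, p, digits = 3) {
  fmt_p <- if (is.finite(p) && p < 1e-4 && p > 0) {
    formatC(p, digits = digits, format = "e")
  } else {
    formatC(p, digits = digits, format = "g")
  }
  sprintf("A(%s;%s)", formatC(f, digits = digits, format = "g"), fmt_p)
}

#' @rdname format_afp
#' @param label A string produced by `format_afp`.
#' @return `parse_afp`: numeric vector `c(f =, p =)`.
#' @export
parse_afp <- function(label) {
  m <- regmatches(label, regexec("^A\\(([^;]+);([^)]+)\\)$", label))[[1]]
  if (length(m) != 3) stop("not an A(F;P) label: ", label, call. = FALSE)
  c(f = as.numeric(m[2]), p = as.numeric(m[3]))
}

#' qPCR Ct table
#'
#' Threshold-cycle values per (sample, gene) with a designated
#' housekeeping reference gene (present in every sample) and a
#' reference sample shared across experiments, against which
#' delta-delta-Ct is formed.
#'
#' @param data data.frame with columns `sample_id`, `gene`,
#'   `ct_cycles`.
#' @param reference_gene Housekeeping gene (default "HPRT").
#' @param reference_sample_id Sample all others are compared to.
#' @return An object of class `ct_table` (a data.frame).
#' @export
ct_table <- function(data, reference_gene = "HPRT",
                     reference_sample_id) {
  need <- c("sample_id", "gene", "ct_cycles")
  if (!all(need %in% names(data))) {
    stop("missing columns: ",
         paste(setdiff(need, names(data)), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(data$ct_cycles))) {
    stop("Ct values must be finite", call. = FALSE)
  }
  samples <- unique(data$sample_id)
  for (s in samples) {
    if (!reference_gene %in% data$gene[data$sample_id == s]) {
      stop(sprintf("sample '%s' lacks the reference gene '%s'",
                   s, reference_gene), call. = FALSE)
    }
  }
  if (!reference_sample_id %in% samples) {
    stop(sprintf("reference sample '%s' not present", reference_sample_id),
         call. = FALSE)
  }
  structure(as.data.frame(data), reference_gene = reference_gene,
            reference_sample_id = reference_sample_id,
            class = c("ct_table", "data.frame"))
}

#' Relative qPCR quantification (delta-delta-Ct)
#'
#' deltaC(s, g) = Ct(s, g) - Ct(s, reference gene);
#' deltadeltaC(s, g) = deltaC(s, g) - deltaC(reference sample, g);
#' fold change = 2^-deltadeltaC. Adding a constant to all Ct values of
#' one sample cancels exactly through the reference gene.
#'
#' @param table A [ct_table()].
#' @return data.frame with `sample_id`, `gene`, `ct_cycles`,
#'   `delta_ct`, `delta_delta_ct`, `fold_change` for every
#'   non-reference gene.
#' @export
ddct <- function(table) {
  stopifnot(inherits(table, "ct_table"))
  ref_gene <- attr(table, "reference_gene")
  ref_sample <- attr(table, "reference_sample_id")
  df <- as.data.frame(table)
  ref_ct <- function(s) {
    v <- df$ct_cycles[df$sample_id == s & df$gene == ref_gene]
    if (length(v) != 1) {
      stop(sprintf("sample '%s' must have exactly one '%s' row", s,
                   ref_gene), call. = FALSE)
    }
    v
  }
  targets <- df[df$gene != ref_gene, , drop = FALSE]
  targets$delta_ct <- targets$ct_cycles -
    vapply(targets$sample_id, ref_ct, 1)
  ref_dc <- targets[targets$sample_id == ref_sample, , drop = FALSE]
  dc_ref_of <- function(g) {
    v <- ref_dc$delta_ct[ref_dc$gene == g]
    if (length(v) != 1) {
      stop(sprintf("reference sample lacks gene '%s'", g), call. = FALSE)
    }
    v
  }
  targets$delta_delta_ct <- targets$delta_ct -
    vapply(targets$gene, dc_ref_of, 1)
  targets$fold_change <- 2^(-targets$delta_delta_ct)
  rownames(targets) <- NULL
  targets
}
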