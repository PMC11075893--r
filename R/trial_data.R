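#' Co-inoculation trial data
#'
#' A host outcome table records, for each host in a co-inoculation trial, the
#' inoculum density it was exposed to and the number of colonies of each
#' fluorescently labelled strain recovered from its symbiotic organ. A host is
#' *colonized* iff at least one colony of either strain was recovered.
#'
#' @name trial_data
#' @keywords internal
NULL

.trial_cols <- c(host_id = "host_id", trial_id = "trial_id",
                 inoculum_density = "inoculum_density_cfu_per_ul",
                 green_count = "green_count", red_count = "red_count")

#' Assemble and validate a host outcome table
#'
#' @param df data.frame with columns `host_id`, `trial_id`,
#'   `inoculum_density` (CFU/uL, positive), `green_count`, `red_count`
#'   (non-negative integer colony counts).
#' @return A `data.frame` of class `host_outcomes` with a derived logical
#'   `colonized` column (`TRUE` iff `green_count + red_count > 0`).
#' @examples
#' host_outcomes(data.frame(host_id = "h1", trial_id = "t1",
#'   inoculum_density = 100, green_count = 12, red_count = 30))
#' @export
host_outcomes <- function(df) {
  need <- names(.trial_cols)
  gd_check(all(need %in% names(df)),
           "missing columns: %s", paste(setdiff(need, names(df)), collapse = ", "),
           class = "gutdrift_bad_input")
  df <- as.data.frame(df)[, union(need, names(df)), drop = FALSE]
  bad_row <- function(ok, what) {
    if (any(!ok)) {
      gd_stop("%s in row(s) %s", what,
              paste(which(!ok), collapse = ", "), class = "gutdrift_bad_input")
    }
  }
  for (col in c("green_count", "red_count")) {
    v <- df[[col]]
    bad_row(is.finite(v) & !is.na(v), sprintf("missing or non-finite %s", col))
    bad_row(v >= 0, sprintf("negative %s", col))
    bad_row(v == floor(v), sprintf("non-integer %s", col))
    df[[col]] <- as.integer(round(v))
  }
  bad_row(is.finite(df$inoculum_density) & df$inoculum_density > 0,
          "non-positive inoculum_density")
  df$colonized <- df$green_count + df$red_count > 0L
  class(df) <- c("host_outcomes", "data.frame")
  df
}

#' Read a co-inoculation trial table from CSV/TSV
#'
#' Expects a header naming five columns (default file names: `host_id`,
#' `trial_id`, `inoculum_density_cfu_per_ul`, `green_count`, `red_count`);
#' the mapping from internal names to file column names is configurable.
#' Rows with missing counts are rejected with the offending row number,
#' never silently dropped.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"tsv"`.
#' @param col_map named character vector mapping internal column names
#'   (`host_id`, `trial_id`, `inoculum_density`, `green_count`, `red_count`)
#'   to file header names.
#' @return a [host_outcomes] table.
#' @export
read_trials <- function(path, dialect = c("csv", "tsv"), col_map = .trial_cols) {
  dialect <- match.arg(dialect)
  gd_check(file.exists(path), "file not found: %s", path,
           class = "gutdrift_io_error")
  raw <- if (dialect == "csv") read.csv(path, check.names = FALSE)
         else read.delim(path, check.names = FALSE)
  gd_check(all(col_map %in% names(raw)),
           "file %s lacks required column(s): %s", path,
           paste(setdiff(col_map, names(raw)), collapse = ", "),
           class = "gutdrift_bad_input")
  df <- raw[, col_map, drop = FALSE]
  names(df) <- names(col_map)
  host_outcomes(df)
}

#' Write a host outcome table in the package CSV dialect
#'
#' Counts round-trip exactly through [read_trials()].
#'
#' @param outcomes a [host_outcomes] table.
#' @param path output file path.
#' @param col_map as in [read_trials()].
#' @return `path`, invisibly.
#' @export
write_trials <- function(outcomes, path, col_map = .trial_cols) {
  out <- as.data.frame(outcomes)[, names(col_map), drop = FALSE]
  names(out) <- col_map
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Proportion of red-strain colonies in a colonized host
#'
#' `red_count / (green_count + red_count)` per host. Uncolonized hosts have no
#' defined proportion; callers must filter them out first.
#'
#' @param outcomes a [host_outcomes] table (or any data.frame with
#'   `green_count`/`red_count`).
#' @return numeric vector of proportions in \[0, 1\].
#' @export
red_fraction <- function(outcomes) {
  tot <- outcomes$green_count + outcomes$red_count
  gd_check(all(tot > 0),
           "red_fraction undefined for uncolonized host(s): row %s",
           paste(which(tot == 0), collapse = ", "),
           class = "gutdrift_undefined_proportion")
  outcomes$red_count / tot
}

#' Treatment group of hosts sharing an inoculum-density bin
#'
#' @param label bin label, e.g. `"1e2"` or `"<1e2"`.
#' @param outcomes a non-empty [host_outcomes] table.
#' @param density_range half-open interval `[low, high)` in CFU/uL containing
#'   every member's inoculum density.
#' @param pooled logical; `TRUE` for a pooled below-threshold group whose
#'   members also appear in their own decade groups.
#' @return object of class `treatment_group`.
#' @export
treatment_group <- function(label, outcomes, density_range, pooled = FALSE) {
  gd_check(nrow(outcomes) > 0, "treatment group '%s' is empty", label,
           class = "gutdrift_bad_input")
  d <- outcomes$inoculum_density
  gd_check(all(d >= density_range[1] & d < density_range[2]),
           "density outside range in group '%s'", label,
           class = "gutdrift_bad_input")
  structure(list(label = label, outcomes = outcomes,
                 density_range = density_range, pooled = pooled),
            class = "treatment_group")
}

#' @export
print.treatment_group <- function(x, ...) {
  cat(sprintf("<treatment_group '%s'%s: %d hosts, density [%g, %g) CFU/uL>\n",
              x$label, if (x$pooled) " (pooled)" else "",
              nrow(x$outcomes), x$density_range[1], x$density_range[2]))
  invisible(x)
}

# decade index k with 10^k <= d < 10^(k+1), robust to log10 rounding at
# exact powers of ten
.decade <- function(d) {
  k <- floor(log10(d))
  k <- ifelse(d < 10^k, k - 1, k)
  ifelse(d >= 10^(k + 1), k + 1, k)
}

.density_label <- function(x) {
  k <- log10(x)
  if (isTRUE(all.equal(k, round(k)))) sprintf("1e%d", as.integer(round(k)))
  else format(x)
}

#' Bin hosts into decade treatment groups
#'
#' Hosts are grouped by the decade of their inoculum density: bin `1e(k)`
#' holds densities in the half-open interval `[10^k, 10^(k+1))`. If
#' `pool_below` is given, all hosts with density strictly below it form one
#' *additional* pooled group labelled `"<label(pool_below)"`; pooled members
#' are duplicated, not removed from their decade groups (recorded in the
#' `pooled` flag of the group).
#'
#' @param outcomes a [host_outcomes] table with positive densities.
#' @param pool_below optional density threshold (CFU/uL).
#' @return named list of [treatment_group] objects, decade groups sorted by
#'   density, pooled group (if any) last.
#' @export
bin_by_decade <- function(outcomes, pool_below = NULL) {
  d <- outcomes$inoculum_density
  gd_check(all(d > 0), "densities must be positive", class = "gutdrift_bad_input")
  k <- .decade(d)
  groups <- lapply(sort(unique(k)), function(ki) {
    treatment_group(sprintf("1e%d", ki), outcomes[k == ki, , drop = FALSE],
                    c(10^ki, 10^(ki + 1)))
  })
  names(groups) <- vapply(groups, `[[`, "", "label")
  if (!is.null(pool_below)) {
    sel <- d < pool_below
    if (any(sel)) {
      lab <- paste0("<", .density_label(pool_below))
      groups[[lab]] <- treatment_group(lab, outcomes[sel, , drop = FALSE],
                                       c(0, pool_below), pooled = TRUE)
    }
  }
  groups
}

#' Colonization success rate of a treatment group
#'
#' @param g a [treatment_group].
#' @return list with integer `colonized`, integer `total`, the exact ratio as
#'   a string, and `fraction = colonized/total`.
#' @export
success_rate <- function(g) {
  gd_check(inherits(g, "treatment_group"), "expected a treatment_group",
           class = "gutdrift_bad_input")
  n_col <- sum(g$outcomes$colonized)
  n_tot <- nrow(g$outcomes)
  list(colonized = as.integer(n_col), total = as.integer(n_tot),
       ratio = sprintf("%d/%d", n_col, n_tot), fraction = n_col / n_tot)
}
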