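# Denoising: clinical-criteria filtering and DBSCAN outlier removal.
#
# Two routes to a reference dataset for model building: exclude
# participants whose LMP is likely unreliable or who carry foetal
# growth-restriction risk (clinical route), or remove low-density points
# in the (CRL, GA_LMP) plane (data-driven route, DBSCAN with eps 0.5 and
# minPts 20 in raw units).

#' Default clinical exclusion criteria
#'
#' Named list of predicates over one observation's covariates. Each
#' predicate is a function of the observation row returning `TRUE` when
#' the row must be EXCLUDED. The default set excludes unreliable LMP,
#' smoking/tobacco/alcohol use, and under-/overweight mothers
#' (BMI < 18.5 or >= 25); the exact study criteria are not public, so the
#' set is fully replaceable.
#'
#' @param bmi_lower,bmi_upper BMI band treated as normal weight.
#' @return Named list of predicate functions.
#' @export
default_clinical_criteria <- function(bmi_lower = 18.5, bmi_upper = 25) {
  flag <- function(col) {
    force(col)
    function(row) isTRUE(as.logical(row[[col]]))
  }
  list(
    unreliable_lmp = flag("unreliable_lmp"),
    smoker = flag("smoker"),
    tobacco = flag("tobacco"),
    alcohol = flag("alcohol"),
    bmi_out_of_band = function(row) {
      b <- row[["bmi"]]
      !is.na(b) && (b < bmi_lower || b >= bmi_upper)
    })
}

#' Clinical-criteria filtering
#'
#' Removes every observation for which at least one enabled criterion
#' fires, and reports per-criterion exclusion counts (an observation
#' excluded by several criteria counts once per criterion; the retained
#' set is the complement of the union). Idempotent by construction.
#'
#' @param cohort A `cohort_table`.
#' @param criteria Named list of predicate functions, as
#'   [default_clinical_criteria()].
#' @return List with `cohort` (filtered, provenance suffixed
#'   `"+clinical"`) and `log` (data frame of per-criterion counts; also
#'   stored in the result's metadata).
#' @export
clinical_filter <- function(cohort, criteria = default_clinical_criteria()) {
  stopifnot(inherits(cohort, "cohort_table"), is.list(criteria))
  obs <- cohort$observations
  n <- nrow(obs)
  fired <- matrix(FALSE, nrow = n, ncol = length(criteria),
                  dimnames = list(NULL, names(criteria)))
  for (j in seq_along(criteria)) {
    pred <- criteria[[j]]
    res <- vapply(seq_len(n), function(i) {
      out <- tryCatch(pred(obs[i, , drop = FALSE]), error = function(e) {
        stop("criterion '", names(criteria)[j],
             "' failed on row ", i, ": ", conditionMessage(e))
      })
      isTRUE(out)
    }, logical(1))
    fired[, j] <- res
  }
  excluded <- rowSums(fired) > 0
  log <- data.frame(criterion = colnames(fired),
                    n_excluded = colSums(fired), row.names = NULL)
  kept <- obs[!excluded, , drop = FALSE]
  rownames(kept) <- NULL
  out <- cohort
  out$observations <- kept
  out$metadata$n_o <- nrow(kept)
  out$metadata$n_p <- length(unique(kept$participant_id))
  out$metadata$provenance <- paste0(cohort$metadata$provenance, "+clinical")
  out$metadata$clinical_filter_log <- log
  out$metadata$n_excluded_clinical <- sum(excluded)
  list(cohort = out, log = log)
}

#' DBSCAN clustering
#'
#' Classic DBSCAN on a 2-column coordinate matrix. A core point has at
#' least `min_points` neighbours within Euclidean distance `eps`
#' (counting itself); clusters are the density-connected components of
#' core points plus their border points; everything else is labelled
#' noise (`0`). Border points reachable from several clusters join the
#' cluster of the lowest-indexed core point that reaches them, making
#' the partition deterministic.
#'
#' @param points_2d Numeric matrix or data frame with 2 columns; finite
#'   coordinates.
#' @param eps Neighbourhood radius (same units as the coordinates).
#' @param min_points Neighbour count threshold (self included).
#' @return Integer vector of cluster labels; `0` means noise.
#' @examples
#' pts <- rbind(matrix(rnorm(100, sd = 0.1), ncol = 2), c(5, 5))
#' table(dbscan_cluster(pts, eps = 0.5, min_points = 10))
#' @export
dbscan_cluster <- function(points_2d, eps = 0.5, min_points = 20) {
  x <- as.matrix(points_2d)
  stopifnot(is.numeric(x), eps > 0, min_points >= 1)
  n <- nrow(x)
  if (n == 0) return(integer(0))
  if (any(!is.finite(x))) stop("non-finite coordinates")

  d2 <- as.matrix(stats::dist(x))^2
  eps2 <- eps^2
  neighbours <- lapply(seq_len(n), function(i) which(d2[i, ] <= eps2))
  n_nb <- lengths(neighbours)
  core <- n_nb >= min_points

  labels <- integer(n) # 0 = unvisited/noise
  cluster_id <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cluster_id <- cluster_id + 1L
    labels[i] <- cluster_id
    queue <- neighbours[[i]]
    head_pos <- 1L
    while (head_pos <= length(queue)) {
      j <- queue[[head_pos]]
      head_pos <- head_pos + 1L
      if (labels[j] == 0L) {
        labels[j] <- cluster_id  # border or core, first-reached wins
        if (core[j]) {
          nb <- neighbours[[j]]
          queue <- c(queue, nb[labels[nb] == 0L])
        }
      }
    }
  }
  labels
}

#' DBSCAN outlier removal on (CRL, GA_LMP)
#'
#' Runs [dbscan_cluster()] on the raw-unit plane (CRL in cm on x,
#' LMP-based GA in weeks on y — `eps = 0.5` is only meaningful on a
#' declared scale, and raw units are the default; set `standardize` to
#' cluster on z-scores instead) and removes rows labelled noise. Rows
#' lacking CRL or GA cannot be density-checked and are removed as well,
#' with their count reported separately.
#'
#' @param cohort A `cohort_table` whose observations carry `crl_cm` and
#'   `ga_lmp_weeks`.
#' @param eps Neighbourhood radius (cm/weeks units by default).
#' @param min_points Neighbour threshold, self included.
#' @param standardize Cluster on per-axis z-scores instead of raw units.
#' @return List: `cohort` (noise removed, provenance suffixed
#'   `"+dbscan"`), `removed` (the noise rows), `labels` (per-complete-row
#'   cluster labels) and `retention` (fraction of complete rows kept).
#' @export
dbscan_filter <- function(cohort, eps = 0.5, min_points = 20,
                          standardize = FALSE) {
  stopifnot(inherits(cohort, "cohort_table"))
  obs <- cohort$observations
  complete <- !is.na(obs$crl_cm) & !is.na(obs$ga_lmp_weeks)
  pts <- cbind(crl = obs$crl_cm[complete], ga = obs$ga_lmp_weeks[complete])
  if (standardize) pts <- scale(pts)
  if (nrow(pts) < min_points) {
    warning("fewer complete rows (", nrow(pts), ") than min_points (",
            min_points, "): all complete rows are noise")
  }
  labels <- dbscan_cluster(pts, eps = eps, min_points = min_points)
  keep_complete <- labels != 0L
  keep <- complete
  keep[complete] <- keep_complete

  out <- cohort
  out$observations <- obs[keep, , drop = FALSE]
  rownames(out$observations) <- NULL
  out$metadata$n_o <- sum(keep)
  out$metadata$n_p <- length(unique(out$observations$participant_id))
  out$metadata$provenance <- paste0(cohort$metadata$provenance, "+dbscan")
  out$metadata$dbscan <- list(eps = eps, min_points = min_points,
                              standardize = standardize,
                              n_noise = sum(!keep_complete),
                              n_incomplete = sum(!complete),
                              retention = mean(keep_complete))
  list(cohort = out,
       removed = obs[!keep, , drop = FALSE],
       labels = labels,
       retention = if (nrow(pts) > 0) mean(keep_complete) else NA_real_)
}
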