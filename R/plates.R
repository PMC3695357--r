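#' 384-well plate analytics
#'
#' Raw ADP-detection kinase assays read out in relative luminescence units
#' (RLU); lower sample signal means more ADP-production was inhibited.  The
#' standard layout places the positive (no kinase reaction) control in
#' columns 1-2 and the negative (no kinase inhibition) control in columns
#' 23-24 of each 384-well plate.
#'
#' @name hts_plates
NULL

PLATE_ROWS <- 16L
PLATE_COLS <- 24L
WELL_ROLES <- c("sample", "pos_ctrl_no_kinase", "neg_ctrl_no_inhibition",
                "ref_inhibitor", "empty")

#' Construct a 384-well plate object
#'
#' @param rlu 16 x 24 numeric matrix of RLU values (non-negative).
#' @param roles 16 x 24 character matrix of well roles (see `WELL_ROLES`);
#'   defaults to the standard layout: columns 1-2 positive (no kinase)
#'   control, columns 23-24 negative (no inhibition) control, rest samples.
#' @param ids 16 x 24 character matrix of compound ids for sample wells
#'   (wells sharing an id form a replicate group); defaults to one id per
#'   sample well.
#' @return object of class `plate`.
#' @export
plate <- function(rlu, roles = default_roles(), ids = NULL) {
  rlu <- as.matrix(rlu)
  stopifnot(nrow(rlu) == PLATE_ROWS, ncol(rlu) == PLATE_COLS,
            all(is.finite(rlu)), all(rlu >= 0),
            nrow(roles) == PLATE_ROWS, ncol(roles) == PLATE_COLS,
            all(roles %in% WELL_ROLES))
  if (is.null(ids)) {
    ids <- matrix(NA_character_, PLATE_ROWS, PLATE_COLS)
    sw <- which(roles == "sample")
    ids[sw] <- sprintf("cmpd_%03d", seq_along(sw))
  }
  if (any(roles == "sample" & (is.na(ids) | !nzchar(ids)))) {
    stop("every sample well needs a compound id", call. = FALSE)
  }
  structure(list(rlu = rlu, roles = roles, ids = ids), class = "plate")
}

#' @rdname plate
#' @export
default_roles <- function() {
  roles <- matrix("sample", PLATE_ROWS, PLATE_COLS)
  roles[, 1:2] <- "pos_ctrl_no_kinase"
  roles[, 23:24] <- "neg_ctrl_no_inhibition"
  roles
}

#' @export
print.plate <- function(x, ...) {
  cat(sprintf("<plate: %d sample wells, %d pos-ctrl, %d neg-ctrl, %d other>\n",
              sum(x$roles == "sample"), sum(x$roles == "pos_ctrl_no_kinase"),
              sum(x$roles == "neg_ctrl_no_inhibition"),
              sum(!x$roles %in% c("sample", "pos_ctrl_no_kinase",
                                  "neg_ctrl_no_inhibition"))))
  invisible(x)
}

#' Control-normalized percent activity
#'
#' `100 * (sample - no-kinase control mean) / (kinase control mean -
#' no-kinase control mean)`; 100% is the uninhibited reaction, 0% the
#' no-kinase background.  Values outside `[0, 100]` are possible and kept.
#'
#' @param sample_rlu numeric vector of sample RLU.
#' @param no_kinase_avg mean RLU of the no-kinase (positive) control.
#' @param kinase_avg mean RLU of the no-inhibition (negative) control.
#' @return numeric vector of percent activity.
#' @export
percent_activity <- function(sample_rlu, no_kinase_avg, kinase_avg) {
  if (isTRUE(all.equal(kinase_avg, no_kinase_avg))) {
    stop("degenerate controls: kinase and no-kinase control means are equal",
         call. = FALSE)
  }
  100 * (sample_rlu - no_kinase_avg) / (kinase_avg - no_kinase_avg)
}

#' Z'-factor plate-quality statistic
#'
#' `Z' = 1 - 3 * (SD_sample + SD_control) / |M_sample - M_control|`.  The
#' attached QC verdict is `"acceptable"` iff Z' is at least `min_zprime`
#' (default 0.6).
#'
#' @param sample_mean,sample_sd,control_mean,control_sd group statistics.
#' @param min_zprime acceptability bound (default 0.6).
#' @return Z' value with an `"acceptable"` attribute.
#' @export
zprime <- function(sample_mean, sample_sd, control_mean, control_sd,
                   min_zprime = 0.6) {
  if (isTRUE(all.equal(sample_mean, control_mean))) {
    stop("degenerate controls: equal group means", call. = FALSE)
  }
  z <- 1 - 3 * (sample_sd + control_sd) / abs(sample_mean - control_mean)
  structure(z, acceptable = z >= min_zprime)
}

#' Plate quality control
#'
#' Window = (no-inhibition control mean) / (no-kinase control mean); the
#' plate passes iff window is at least `min_window` (default 6) and the
#' control Z' is at least `min_zprime` (default 0.6).  Swapped controls
#' (negative below positive) trigger a warning and fail.
#'
#' @param p a `plate`.
#' @param min_window,min_zprime QC bounds.
#' @return list of class `plate_stats`.
#' @export
plate_qc <- function(p, min_window = 6, min_zprime = 0.6) {
  stopifnot(inherits(p, "plate"))
  pos <- p$rlu[p$roles == "pos_ctrl_no_kinase"]
  neg <- p$rlu[p$roles == "neg_ctrl_no_inhibition"]
  if (!length(pos) || !length(neg)) {
    stop("missing control group in plate layout", call. = FALSE)
  }
  pos_mean <- mean(pos); pos_sd <- stats::sd(pos)
  neg_mean <- mean(neg); neg_sd <- stats::sd(neg)
  swapped <- neg_mean < pos_mean
  if (swapped) {
    warning("controls appear swapped: no-inhibition mean below no-kinase mean",
            call. = FALSE)
  }
  window <- neg_mean / pos_mean
  z <- zprime(neg_mean, neg_sd, pos_mean, pos_sd, min_zprime)
  structure(list(pos_mean = pos_mean, pos_sd = pos_sd,
                 neg_mean = neg_mean, neg_sd = neg_sd,
                 window = window, zprime = as.numeric(z),
                 pass = !swapped && window >= min_window &&
                   as.numeric(z) >= min_zprime,
                 swapped = swapped,
                 sd_definition = "sample sd (n-1 denominator)"),
            class = "plate_stats")
}

#' @export
print.plate_stats <- function(x, ...) {
  cat(sprintf("<plate_stats: window %.2f, Z' %.3f -> %s>\n",
              x$window, x$zprime, if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Call primary screening hits on a plate
#'
#' The plate run mean and standard deviation are computed over sample wells
#' only (controls, reference-inhibitor and empty wells excluded); a compound
#' is a hit when its replicate-mean RLU is at least `k` standard deviations
#' below that mean (lower signal = inhibition).  Results are sorted by mean
#' RLU ascending.
#'
#' @param p a `plate`.
#' @param k SD multiplier (default 3).
#' @param aggregate aggregate replicates by compound id before calling
#'   (default TRUE); with FALSE every well is called individually.
#' @return data frame of class `hit_calls`: compound, mean_rlu, n_wells,
#'   is_hit, plus `plate_mean`, `plate_sd` and `threshold` attributes.
#' @export
call_hits <- function(p, k = 3, aggregate = TRUE) {
  stopifnot(inherits(p, "plate"))
  sw <- p$roles == "sample"
  vals <- p$rlu[sw]
  if (length(vals) < 2L) {
    stop("need at least 2 sample wells", call. = FALSE)
  }
  m <- mean(vals)
  s <- stats::sd(vals)
  if (!is.finite(s) || s == 0) {
    stop("degenerate plate: zero sample standard deviation", call. = FALSE)
  }
  thr <- m - k * s
  if (aggregate) {
    grp <- split(vals, p$ids[sw])
    out <- data.frame(
      compound = names(grp),
      mean_rlu = vapply(grp, mean, numeric(1)),
      n_wells = vapply(grp, length, integer(1)),
      stringsAsFactors = FALSE
    )
  } else {
    out <- data.frame(compound = p$ids[sw], mean_rlu = vals, n_wells = 1L,
                      stringsAsFactors = FALSE)
  }
  out$is_hit <- out$mean_rlu <= thr
  out <- out[order(out$mean_rlu), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, plate_mean = m, plate_sd = s, threshold = thr,
            class = c("hit_calls", "data.frame"))
}

#' Read a plate from long-format CSV
#'
#' Expects columns `row`, `col`, `rlu` and optionally `role` and
#' `compound`; wells absent from the file are marked `empty`.
#'
#' @param path CSV file.
#' @return a `plate`.
#' @export
read_plate_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("row", "col", "rlu") %in% names(d)))
  rlu <- matrix(0, PLATE_ROWS, PLATE_COLS)
  roles <- matrix("empty", PLATE_ROWS, PLATE_COLS)
  ids <- matrix(NA_character_, PLATE_ROWS, PLATE_COLS)
  idx <- cbind(d$row, d$col)
  rlu[idx] <- d$rlu
  roles[idx] <- if ("role" %in% names(d)) d$role else "sample"
  if ("compound" %in% names(d)) {
    ids[idx] <- d$compound
  } else {
    sw <- which(roles == "sample")
    ids[sw] <- sprintf("cmpd_%03d", seq_along(sw))
  }
  ids[roles != "sample"] <- NA_character_
  plate(rlu, roles, ids)
}

#' Write a plate to long-format CSV
#'
#' @param p a `plate`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(p, path) {
  idx <- which(p$roles != "empty", arr.ind = TRUE)
  d <- data.frame(row = idx[, 1], col = idx[, 2],
                  rlu = p$rlu[idx], role = p$roles[idx],
                  compound = p$ids[idx], stringsAsFactors = FALSE)
  d <- d[order(d$row, d$col), ]
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
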