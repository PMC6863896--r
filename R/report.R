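# Round half away from zero, matching the printed one-decimal style of
# clinical tables (base round() rounds half to even).
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Cohort summary of 2D and 3D lesion counts
#'
#' Per-eye descriptive statistics for each detection modality and shape
#' percentages across all 3D lesions, reproducing the arithmetic of a
#' clinical characteristics table: totals, per-eye mean and sample
#' standard deviation (n-1; reported as 0 with `sd_defined = FALSE` for a
#' single eye), range, shape counts with one-decimal percentages, and
#' type 1 MNV co-presence.
#'
#' @param lesions_2d Integer vector: 2D en face lesion count per eye.
#' @param lesions_3d List (one element per eye) of character vectors of
#'   3D lesion shape classes (`"saccular"` / `"filiform"`), e.g. from the
#'   `shape_class` column of [characterize_lesions()]. An eye with no
#'   lesions contributes `character(0)`.
#' @param t1_mnv Logical vector per eye: associated type 1 MNV present.
#' @param icga Optional integer vector per eye: lesions identified on
#'   indocyanine green angiography.
#' @return Object of class `octa_summary` (a list; see fields in the
#'   implementation), printable with `print()`.
#' @export
summarize_lesions <- function(lesions_2d, lesions_3d, t1_mnv, icga = NULL) {
  n_eyes <- length(lesions_3d)
  if (n_eyes < 1) stop("at least one eye is required")
  if (length(lesions_2d) != n_eyes || length(t1_mnv) != n_eyes)
    stop("`lesions_2d`, `lesions_3d` and `t1_mnv` must have one entry per eye")
  if (!is.null(icga) && length(icga) != n_eyes)
    stop("`icga` must have one entry per eye")

  counts_3d <- vapply(lesions_3d, length, integer(1))
  shapes <- unlist(lesions_3d, use.names = FALSE)
  bad <- setdiff(unique(shapes), c("saccular", "filiform"))
  if (length(bad) > 0)
    stop(sprintf("unknown shape class: %s", paste(bad, collapse = ", ")))

  per_eye <- function(x) {
    s <- if (length(x) > 1) sd(x) else 0
    list(mean = round_half_away(mean(x)),
         sd = round_half_away(s),
         sd_defined = length(x) > 1,
         min = round_half_away(min(x)),
         max = round_half_away(max(x)))
  }

  n3 <- sum(counts_3d)
  n_sac <- sum(shapes == "saccular")
  n_fil <- sum(shapes == "filiform")
  out <- list(
    n_eyes = n_eyes,
    n_lesions_2d = sum(lesions_2d),
    n_lesions_3d = n3,
    per_eye_2d = per_eye(as.numeric(lesions_2d)),
    per_eye_3d = per_eye(as.numeric(counts_3d)),
    n_saccular = n_sac,
    n_filiform = n_fil,
    pct_saccular = if (n3 > 0) round_half_away(100 * n_sac / n3) else NA_real_,
    pct_filiform = if (n3 > 0) round_half_away(100 * n_fil / n3) else NA_real_,
    n_eyes_with_t1_mnv = sum(t1_mnv),
    pct_eyes_with_t1_mnv = round_half_away(100 * sum(t1_mnv) / n_eyes),
    sd_note = "sample standard deviation (n-1)")
  if (!is.null(icga)) {
    out$n_lesions_icga <- sum(icga)
    out$per_eye_icga <- per_eye(as.numeric(icga))
  }
  structure(out, class = "octa_summary")
}

#' @export
print.octa_summary <- function(x, ...) {
  cat(sprintf("Eyes: %d\n", x$n_eyes))
  cat(sprintf("Type 1 MNV co-presence: %d (%.1f%%)\n",
              x$n_eyes_with_t1_mnv, x$pct_eyes_with_t1_mnv))
  cat(sprintf("Lesions on 2D en face OCTA: %d [mean %.1f +/- %.1f, range %.1f-%.1f]\n",
              x$n_lesions_2d, x$per_eye_2d$mean, x$per_eye_2d$sd,
              x$per_eye_2d$min, x$per_eye_2d$max))
  cat(sprintf("Lesions on 3D OCTA: %d [mean %.1f +/- %.1f, range %.1f-%.1f]\n",
              x$n_lesions_3d, x$per_eye_3d$mean, x$per_eye_3d$sd,
              x$per_eye_3d$min, x$per_eye_3d$max))
  cat(sprintf("  saccular %d (%.1f%%), filiform %d (%.1f%%)\n",
              x$n_saccular, x$pct_saccular, x$n_filiform, x$pct_filiform))
  if (!is.null(x$n_lesions_icga))
    cat(sprintf("Lesions on ICGA: %d [mean %.1f +/- %.1f]\n",
                x$n_lesions_icga, x$per_eye_icga$mean, x$per_eye_icga$sd))
  invisible(x)
}

#' Compare 2D and 3D detection
#'
#' Absolute and per-eye detection difference and the 3D/2D ratio
#' (`NA` when no 2D lesions were detected).
#'
#' @param summary An `octa_summary` from [summarize_lesions()].
#' @return List with `n_2d`, `n_3d`, `difference`, `difference_per_eye`,
#'   `ratio`.
#' @export
compare_2d_3d <- function(summary) {
  stopifnot(inherits(summary, "octa_summary"))
  n2 <- summary$n_lesions_2d
  n3 <- summary$n_lesions_3d
  list(n_2d = n2, n_3d = n3,
       difference = n3 - n2,
       difference_per_eye = round_half_away((n3 - n2) / summary$n_eyes),
       ratio = if (n2 > 0) n3 / n2 else NA_real_)
}

#' Export a cohort summary as JSON or CSV
#'
#' @param summary An `octa_summary`.
#' @param path Output path; format chosen by extension (`.json` or
#'   `.csv`).
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  stopifnot(inherits(summary, "octa_summary"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE, digits = NA)
  } else {
    flat <- unlist(unclass(summary))
    write.csv(data.frame(field = names(flat), value = unname(flat)),
              path, row.names = FALSE)
  }
  invisible(path)
}
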