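# printed marginals of the mammographic-mass attributes (mean, sd, min, max)
mammo_marginals <- function() {
  data.frame(
    attribute = c("birads", "age", "shape", "margin", "density"),
    mean = c(4.33, 55.78, 2.78, 2.81, 2.92),
    sd   = c(0.63, 14.67, 1.24, 1.57, 0.35),
    min  = c(1, 18, 1, 1, 1),
    max  = c(6, 96, 4, 5, 4))
}

#' Read a mammographic-mass CSV file
#'
#' Parses the UCI dialect: six comma-separated fields per line
#' (BI-RADS, age, shape, margin, density, severity), no header, `?` for
#' a missing value.  Lines starting with `#` are treated as comments
#' (the synthetic writer embeds provenance there).  No cleaning is
#' applied; missing values become `NA` and are tallied per field.
#'
#' @param path file path.
#' @param col_names column order of the file; change it if your copy
#'   deviates from the stock 6-column layout.
#' @return a data.frame of class `mammo_data` with integer-valued
#'   columns and an attribute `missing_counts` (named integer vector).
#' @export
read_mammo_csv <- function(path,
                           col_names = c("birads", "age", "shape",
                                         "margin", "density", "severity")) {
  stopifnot(length(col_names) == 6L)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  parts <- strsplit(lines[keep], ",", fixed = TRUE)
  bad <- which(lengths(parts) != 6L)
  if (length(bad))
    stop(sprintf("line %d: expected 6 comma-separated fields, got %d",
                 lineno[bad[1L]], lengths(parts)[bad[1L]]))
  m <- matrix(trimws(unlist(parts)), ncol = 6L, byrow = TRUE)
  m[m == "?"] <- NA
  df <- as.data.frame(apply(m, 2L, as.numeric, simplify = FALSE))
  names(df) <- col_names
  miss <- vapply(df, function(col) sum(is.na(col)), integer(1))
  structure(df, missing_counts = miss, class = c("mammo_data", "data.frame"))
}

#' Clean mammographic-mass records into a training set
#'
#' Drops every record with a missing field, then applies the range rule
#' for outliers: a record is removed when any ordinal field falls
#' outside the printed attribute ranges (BI-RADS 1--6, shape 1--4,
#' margin 1--5, density 1--4, age 18--96) or severity is not 0/1.
#'
#' Cleaning is a pure row filter, hence order-independent and
#' idempotent.
#'
#' @param records a `mammo_data` data.frame from [read_mammo_csv()] (or
#'   any data.frame with the six columns).
#' @return a `training_set`: list with `features` (numeric matrix, columns
#'   birads/age/shape/margin/density) and `targets` (0/1 severity).
#' @export
clean_mammo <- function(records) {
  df <- as.data.frame(records)
  need <- c("birads", "age", "shape", "margin", "density", "severity")
  stopifnot(all(need %in% names(df)))
  df <- df[stats::complete.cases(df[need]), need, drop = FALSE]
  rng <- mammo_marginals()
  ok <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(rng))) {
    v <- df[[rng$attribute[i]]]
    ok <- ok & v >= rng$min[i] & v <= rng$max[i]
  }
  ok <- ok & df$severity %in% c(0, 1)
  df <- df[ok, , drop = FALSE]
  if (nrow(df) == 0L) stop("no records survived cleaning")
  training_set(as.matrix(df[, need[1:5]]), df$severity)
}

#' Construct a training set
#'
#' @param features numeric matrix, samples in rows.
#' @param targets numeric vector of 0/1 labels.
#' @return list of class `training_set`.
#' @export
training_set <- function(features, targets) {
  features <- as.matrix(features)
  targets <- as.numeric(targets)
  stopifnot(nrow(features) == length(targets), length(targets) > 0,
            all(targets %in% c(0, 1)))
  structure(list(features = features, targets = targets),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set> %d samples x %d features, %d positive\n",
              nrow(x$features), ncol(x$features), sum(x$targets)))
  invisible(x)
}

#' Generate a feasible SFP instance with a known solution
#'
#' Draws a Gaussian operator A, plants a solution \eqn{\omega^*} strictly
#' inside the chosen norm ball C (scaled to `interior` times the radius),
#' and sets Q so that it contains \eqn{A\omega^*}: either the singleton
#' \eqn{\{A\omega^*\}} or a Euclidean ball of radius `q_radius` around
#' it.  By construction the solution set is nonempty and the instance
#' stores \eqn{\omega^*}.
#'
#' @param m,n operator dimensions (rows, columns).
#' @param constraint `"l2_ball"` or `"l1_ball"` for C.
#' @param gamma norm budget of C; defaults to the study's settings
#'   (17 for L2, 7 for L1).
#' @param q_kind `"singleton"` or `"ball"` for Q.
#' @param q_radius radius of the Q ball when `q_kind = "ball"`.
#' @param interior fraction of the constraint radius at which the
#'   solution is planted (strictly inside for values < 1).
#' @param seed integer seed.
#' @return an [sfp_instance()] with `known_solution` set.
#' @export
make_sfp_instance <- function(m = 20L, n = 10L,
                              constraint = c("l2_ball", "l1_ball"),
                              gamma = NULL,
                              q_kind = c("singleton", "ball"),
                              q_radius = 0.1, interior = 0.8, seed = 1L) {
  constraint <- match.arg(constraint)
  q_kind <- match.arg(q_kind)
  if (is.null(gamma)) gamma <- if (constraint == "l2_ball") 17 else 7
  stopifnot(gamma > 0, interior > 0, interior < 1)
  dat <- with_seed(seed, {
    A <- matrix(stats::rnorm(m * n), m, n)
    z <- stats::rnorm(n)
    list(A = A, z = z)
  })
  wstar <- if (constraint == "l2_ball") {
    interior * sqrt(gamma) * dat$z / sqrt(sum(dat$z^2))
  } else {
    interior * gamma * dat$z / sum(abs(dat$z))
  }
  Cset <- if (constraint == "l2_ball") cc_l2_ball(gamma) else cc_l1_ball(gamma)
  Aw <- drop(dat$A %*% wstar)
  Qset <- if (q_kind == "singleton") cc_singleton(Aw)
          else cc_ball(Aw, q_radius)
  sfp_instance(dat$A, Cset, Qset, known_solution = wstar)
}

#' Generate a labelled feature table with mammographic-mass marginals
#'
#' Two-class Gaussian-cluster generator emulating the printed attribute
#' overview of the mammographic-mass data: five integer-valued features
#' (BI-RADS, age, shape, margin, density) with the printed means and
#' standard deviations as overall marginals, and a binary severity
#' label.  Class means are displaced symmetrically about the marginal
#' mean along every feature by `separation` pooled standard deviations;
#' within-class variance is shrunk so that the overall variance matches
#' the marginal when possible (feasible for moderate separation; for
#' large planted separations the within-class sd is floored at 20% of
#' the marginal sd and the overall sd exceeds the target).
#'
#' Defaults mirror the real table: 961 samples, 445 malignant
#' (class balance 0.463), and `separation = 1`, a moderate overlap at
#' which a well-trained classifier plateaus in the mid-80s accuracy
#' range like the published benchmark.
#'
#' @param n_samples number of rows.
#' @param class_balance fraction of positive (malignant) samples.
#' @param separation distance between class means in pooled-sd units,
#'   applied to every feature.
#' @param marginals data.frame with columns attribute/mean/sd/min/max;
#'   defaults to the printed table.
#' @param round_integers round features to integers and clip into the
#'   printed ranges (the real attributes are integer-valued); disable to
#'   obtain the untruncated Gaussian draws (used e.g. for moment checks).
#' @param seed integer seed.
#' @return a [training_set()].
#' @export
make_classification_table <- function(n_samples = 961L,
                                      class_balance = 445 / 961,
                                      separation = 1,
                                      marginals = mammo_marginals(),
                                      round_integers = TRUE,
                                      seed = 1L) {
  stopifnot(n_samples > 0, class_balance > 0, class_balance < 1,
            separation >= 0)
  p <- class_balance
  n_pos <- round(n_samples * p)
  y <- c(rep(1, n_pos), rep(0, n_samples - n_pos))
  # between-class variance for symmetric displacement d*sd about the mean:
  # p(1-p) d^2 sd^2; shrink within-class variance to preserve the marginal
  shrink2 <- max(1 - p * (1 - p) * separation^2, 0.04)
  X <- with_seed(seed, {
    cols <- lapply(seq_len(nrow(marginals)), function(j) {
      mu <- marginals$mean[j]; s <- marginals$sd[j]
      ctr <- mu + ifelse(y == 1, (1 - p), -p) * separation * s
      v <- stats::rnorm(n_samples, ctr, s * sqrt(shrink2))
      if (round_integers)
        v <- pmin(pmax(round(v), marginals$min[j]), marginals$max[j])
      v
    })
    do.call(cbind, cols)
  })
  colnames(X) <- marginals$attribute
  perm <- with_seed(seed + 1L, sample.int(n_samples))
  training_set(X[perm, , drop = FALSE], y[perm])
}

#' Write a training set in the mammographic-mass CSV dialect
#'
#' Six comma-separated columns (features then severity), no header,
#' with optional `#`-prefixed provenance comments that
#' [read_mammo_csv()] skips.
#'
#' @param data a [training_set()] with five feature columns.
#' @param path output file.
#' @param comments character vector written as leading `# ` lines.
#' @return `path`, invisibly.
#' @export
write_mammo_csv <- function(data, path, comments = character()) {
  stopifnot(inherits(data, "training_set"), ncol(data$features) == 5L)
  body <- apply(cbind(data$features, data$targets), 1L,
                function(r) paste(format(r, trim = TRUE, scientific = FALSE),
                                  collapse = ","))
  writeLines(c(if (length(comments)) paste("#", comments), body), path)
  invisible(path)
}
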