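# Core-group clustering into convergence clubs and adjacent-club merging.

#' Construct a club partition
#'
#' @param clubs list of clubs, each a list with `members` (character
#'   vector) and `test` (a `logt_result` or `NULL` for singletons).
#' @param divergent list with `members` (character vector, possibly empty)
#'   and `test` (diagnostic `logt_result` when size >= 2, else `NULL`).
#' @param units all panel units (for the disjoint-cover check).
#' @param stage `"initial"`, `"merged"` or `"final"`.
#' @return An object of class `club_partition`.
#' @export
club_partition <- function(clubs, divergent, units,
                           stage = c("initial", "merged", "final")) {
  stage <- match.arg(stage)
  all_members <- c(unlist(lapply(clubs, `[[`, "members")),
                   divergent$members)
  if (anyDuplicated(all_members))
    stop("clubs and divergent set must be disjoint; duplicated: ",
         paste(unique(all_members[duplicated(all_members)]), collapse = ", "))
  if (!setequal(all_members, units))
    stop("clubs + divergent set must cover exactly the panel units")
  structure(list(clubs = clubs, divergent = divergent, stage = stage,
                 units = units),
            class = "club_partition")
}

#' @export
print.club_partition <- function(x, ...) {
  cat(sprintf("club_partition (%s): %d club(s), %d divergent unit(s)\n",
              x$stage, length(x$clubs), length(x$divergent$members)))
  for (i in seq_along(x$clubs)) {
    cl <- x$clubs[[i]]
    stat <- if (!is.null(cl$test))
      sprintf("  [gamma %.3f, t %.3f]", cl$test$gamma_hat, cl$test$t_gamma)
    else ""
    cat(sprintf("  Club %d (%d): %s%s\n", i, length(cl$members),
                paste(cl$members, collapse = " | "), stat))
  }
  if (length(x$divergent$members))
    cat(sprintf("  Divergent (%d): %s\n", length(x$divergent$members),
                paste(x$divergent$members, collapse = " | ")))
  invisible(x)
}

#' Order units for core-group search
#'
#' The default rule sorts units by their final-period observation,
#' descending; ties break alphabetically by unit identifier so the
#' ordering is reproducible. The `"mean_last_half"` alternative sorts by
#' the mean over the second half of the sample (t > T/2), which is less
#' sensitive to a noisy final year.
#'
#' @param p a `panel_series`.
#' @param rule `"last_obs"` (default) or `"mean_last_half"`.
#' @return Character vector of unit identifiers in search order.
#' @export
order_units <- function(p, rule = c("last_obs", "mean_last_half")) {
  rule <- match.arg(rule)
  T_ <- length(p$times)
  key <- switch(rule,
    last_obs = p$values[, T_],
    mean_last_half = rowMeans(p$values[, (floor(T_ / 2) + 1L):T_,
                                       drop = FALSE]))
  p$units[order(-key, p$units)]
}

# t-statistic of the log-t test on a unit subset; -Inf when the fit is
# degenerate (e.g. all members identical) so such subsets never qualify.
logt_t_of <- function(p, members, r, hac_lags, L_form) {
  tryCatch(
    logt_fit(p$values[members, , drop = FALSE], r = r, hac_lags = hac_lags,
             L_form = L_form)$t_gamma,
    error = function(e) -Inf)
}

#' Form the core convergence group
#'
#' Walks the ordered units: for the top unit k and each club size
#' R = 2..(n - k + 1), fits the log-t test on units k..k+R-1 and picks the
#' size R* maximizing t_gamma among sizes with t_gamma above `c_star`. If
#' no size qualifies from the top unit, that unit is set aside and the
#' search restarts from the next one. An empty core (no qualifying pair
#' anywhere) is a valid outcome.
#'
#' @param p a `panel_series`.
#' @param ordering unit ordering from [order_units()] (computed if `NULL`).
#' @param c_star core-formation criterion (default -1.65).
#' @inheritParams logt_regression
#' @return Character vector of core members (possibly empty).
#' @export
form_core <- function(p, ordering = NULL, c_star = -1.65, r = 0.3,
                      hac_lags = NULL, L_form = "log") {
  if (is.null(ordering)) ordering <- order_units(p)
  n <- length(ordering)
  for (start in 1:(n - 1L)) {
    sizes <- 2:(n - start + 1L)
    tvals <- vapply(sizes, function(R) {
      logt_t_of(p, ordering[start:(start + R - 1L)], r, hac_lags, L_form)
    }, numeric(1))
    ok <- tvals > c_star
    if (any(ok)) {
      R_star <- sizes[which(tvals == max(tvals[ok]))[1]]
      return(ordering[start:(start + R_star - 1L)])
    }
  }
  character(0)
}

#' Sieve remaining units for club membership
#'
#' Each unit outside the core is appended to the core one at a time (in
#' the supplied search order); it is accepted when the log-t t-statistic
#' of core-plus-unit exceeds `c_star`. The club is the core plus all
#' accepted units. The extended club is then re-tested as a whole against
#' `critical`; if it fails, the sieve is repeated with a stepwise-raised
#' criterion (+0.5 per step) until the club passes or shrinks back to the
#' core, so a reported club always satisfies the club-level test.
#'
#' @param p a `panel_series`.
#' @param core character vector of core members (non-empty).
#' @param candidates units to sieve, in search order; defaults to all
#'   non-core units in [order_units()] order.
#' @param c_star membership criterion (default -1.65).
#' @param critical club-level verification criterion (default -1.65).
#' @inheritParams logt_regression
#' @return Character vector: the club members (core first).
#' @export
sieve_members <- function(p, core, candidates = NULL, c_star = -1.65,
                          critical = -1.65, r = 0.3, hac_lags = NULL,
                          L_form = "log") {
  if (!length(core)) stop("core group is empty")
  if (is.null(candidates))
    candidates <- setdiff(order_units(p), core)
  if (!length(candidates)) return(core)
  c_cur <- c_star
  repeat {
    t_one <- vapply(candidates, function(u) {
      logt_t_of(p, c(core, u), r, hac_lags, L_form)
    }, numeric(1))
    ok <- !is.na(t_one) & t_one > c_cur
    accepted <- candidates[ok]
    club <- c(core, accepted)
    if (!length(accepted)) return(core)
    if (logt_t_of(p, club, r, hac_lags, L_form) > critical) return(club)
    # stepwise-raised criterion; the max() guarantees at least one
    # candidate drops per pass so the loop always terminates
    c_cur <- max(c_cur + 0.5, min(t_one[ok]) + 1e-9)
  }
}

#' Identify convergence clubs by repeated core-group clustering
#'
#' Runs the four-step clustering on the panel: (1) order units by the
#' final observation, (2) form a core group maximizing the log-t
#' t-statistic, (3) sieve the remaining units into the club, (4) test the
#' leftover units jointly -- if they converge they form the last club,
#' otherwise steps 1-3 repeat on them. Units never assigned to any club
#' form the divergent set; a singleton remainder is always divergent
#' (the test is undefined for one unit). Every emitted club of size >= 2
#' is re-verified with the full log-t regression.
#'
#' @param p a `panel_series`.
#' @param c_star core/sieve criterion (default -1.65).
#' @param critical club-verification and divergence criterion.
#' @param ordering_rule passed to [order_units()].
#' @inheritParams logt_regression
#' @param trace logical; print one line per algorithm decision.
#' @return A `club_partition` with `stage = "initial"`.
#' @export
club_cluster <- function(p, c_star = -1.65, critical = -1.65, r = 0.3,
                         hac_lags = NULL, L_form = "log",
                         ordering_rule = "last_obs", trace = FALSE) {
  stopifnot(inherits(p, "panel_series"))
  say <- function(...) if (trace) message(sprintf(...))
  remaining <- p$units
  clubs <- list()
  divergent <- character(0)

  while (length(remaining) >= 2L) {
    sub <- subset_units(p, remaining)
    if (length(clubs) > 0L) {
      t_all <- logt_t_of(sub, remaining, r, hac_lags, L_form)
      if (t_all > critical) {
        say("remainder (%d units) converges jointly (t = %.3f): last club",
            length(remaining), t_all)
        clubs <- c(clubs, list(list(members =
          order_units(sub, ordering_rule))))
        remaining <- character(0)
        break
      }
    }
    ordering <- order_units(sub, ordering_rule)
    core <- form_core(sub, ordering, c_star = c_star, r = r,
                      hac_lags = hac_lags, L_form = L_form)
    if (!length(core)) {
      say("no qualifying core among %d remaining units: all divergent",
          length(remaining))
      divergent <- c(divergent, remaining)
      remaining <- character(0)
      break
    }
    say("core: %s", paste(core, collapse = ", "))
    club <- sieve_members(sub, core, candidates = setdiff(ordering, core),
                          c_star = c_star, critical = critical, r = r,
                          hac_lags = hac_lags, L_form = L_form)
    say("club %d: %s", length(clubs) + 1L, paste(club, collapse = ", "))
    clubs <- c(clubs, list(list(members = club)))
    remaining <- setdiff(remaining, club)
  }
  if (length(remaining) == 1L) divergent <- c(divergent, remaining)

  finalize_partition(p, clubs, divergent, stage = "initial", r = r,
                     hac_lags = hac_lags, L_form = L_form,
                     critical = critical)
}

# Attach verification log-t fits to each club (and a diagnostic fit to a
# divergent set of size >= 2), then build the validated partition object.
finalize_partition <- function(p, clubs, divergent, stage, r, hac_lags,
                               L_form, critical) {
  clubs <- lapply(clubs, function(cl) {
    test <- if (length(cl$members) >= 2L)
      tryCatch(logt_fit(p$values[cl$members, , drop = FALSE], r = r,
                        hac_lags = hac_lags, critical = critical,
                        L_form = L_form),
               error = function(e) NULL)
    list(members = cl$members, test = test)
  })
  div_test <- if (length(divergent) >= 2L)
    tryCatch(logt_fit(p$values[divergent, , drop = FALSE], r = r,
                      hac_lags = hac_lags, critical = critical,
                      L_form = L_form),
             error = function(e) NULL)
  club_partition(clubs,
                 divergent = list(members = divergent, test = div_test),
                 units = p$units, stage = stage)
}

#' Merge adjacent convergence clubs
#'
#' Tests each adjacent club pair (1,2), (2,3), ... with the log-t
#' regression on their union; when the union converges (t_gamma above
#' `critical`) the pair is merged and the pass restarts from the top of
#' the updated list, so chains of fragments of one true club merge
#' transitively. Terminates when a full pass makes no merge. The divergent
#' set is untouched. Applied to an already-final partition it returns it
#' unchanged (idempotent).
#'
#' @param p the `panel_series` the partition was computed on.
#' @param part a `club_partition`.
#' @param critical merge criterion (default -1.65).
#' @inheritParams logt_regression
#' @param trace logical; log each merge test.
#' @return A `club_partition` with `stage = "final"`; attribute
#'   `"merge_log"` is a data.frame of every adjacent test performed.
#' @export
merge_clubs <- function(p, part, critical = -1.65, r = 0.3,
                        hac_lags = NULL, L_form = "log", trace = FALSE) {
  stopifnot(inherits(p, "panel_series"), inherits(part, "club_partition"))
  say <- function(...) if (trace) message(sprintf(...))
  members <- lapply(part$clubs, `[[`, "members")
  log_rows <- list()
  i <- 1L
  while (i < length(members)) {
    pair <- c(members[[i]], members[[i + 1L]])
    t_u <- logt_t_of(p, pair, r, hac_lags, L_form)
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      club_a = i, club_b = i + 1L, t_stat = t_u, merged = t_u > critical)
    if (t_u > critical) {
      say("merge clubs %d + %d (t = %.3f)", i, i + 1L, t_u)
      members[[i]] <- pair
      members[[i + 1L]] <- NULL
      i <- 1L
    } else {
      say("keep clubs %d, %d separate (t = %.3f)", i, i + 1L, t_u)
      i <- i + 1L
    }
  }
  out <- finalize_partition(p, lapply(members, function(m) list(members = m)),
                            part$divergent$members, stage = "final",
                            r = r, hac_lags = hac_lags, L_form = L_form,
                            critical = critical)
  attr(out, "merge_log") <- if (length(log_rows))
    do.call(rbind, log_rows) else
    data.frame(club_a = integer(0), club_b = integer(0),
               t_stat = numeric(0), merged = logical(0))
  out
}

#' Tabular report of a club partition
#'
#' One row per club (divergent set last), mirroring the usual club-table
#' layout: label, size, member list, log-t coefficient, SE, t-statistic.
#'
#' @param part a `club_partition`.
#' @return A data.frame.
#' @export
club_report <- function(part) {
  stopifnot(inherits(part, "club_partition"))
  row_of <- function(label, members, test) {
    data.frame(club = label, size = length(members),
               members = paste(members, collapse = " | "),
               coeff = if (!is.null(test)) test$gamma_hat else NA_real_,
               se = if (!is.null(test)) test$se_gamma else NA_real_,
               t_stat = if (!is.null(test)) test$t_gamma else NA_real_)
  }
  rows <- lapply(seq_along(part$clubs), function(i) {
    row_of(sprintf("Club %d", i), part$clubs[[i]]$members,
           part$clubs[[i]]$test)
  })
  if (length(part$divergent$members))
    rows <- c(rows, list(row_of("Divergent", part$divergent$members,
                                part$divergent$test)))
  out <- do.call(rbind, rows)
  attr(out, "stage") <- part$stage
  out
}

#' Serialize a club partition to JSON
#'
#' @param part a `club_partition`.
#' @param path optional output path.
#' @return JSON string (invisibly when written to file).
#' @export
partition_to_json <- function(part, path = NULL) {
  stopifnot(inherits(part, "club_partition"))
  obj <- list(
    stage = part$stage,
    clubs = lapply(part$clubs, function(cl) {
      list(members = cl$members,
           coeff = if (!is.null(cl$test)) cl$test$gamma_hat else NULL,
           se = if (!is.null(cl$test)) cl$test$se_gamma else NULL,
           t_stat = if (!is.null(cl$test)) cl$test$t_gamma else NULL)
    }),
    divergent = list(
      members = part$divergent$members,
      t_stat = if (!is.null(part$divergent$test))
        part$divergent$test$t_gamma else NULL))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
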