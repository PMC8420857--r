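#' Assignment-stage configuration
#'
#' @param lambda_seg Weight of one segment-count mismatch relative to one
#'   residue-count mismatch in the discrepancy objective (default 1).
#' @param max_moves Cap on phase-2 local moves; default `10 * n_res` chosen
#'   at run time.
#' @return A list of class `assign_config`.
#' @export
assign_config <- function(lambda_seg = 1, max_moves = NULL) {
  structure(list(lambda_seg = lambda_seg, max_moves = max_moves),
            class = "assign_config")
}

#' A per-residue secondary-structure assignment
#'
#' @param labels Character string over `{H, E, C}` (helix, strand, other).
#' @param provenance Optional list recording how the assignment was made
#'   (targets, achieved discrepancy, method).
#' @return An object of class `ss_assignment`.
#' @export
ss_assignment <- function(labels, provenance = list()) {
  labels <- toupper(as.character(labels))
  if (grepl("[^HEC]", labels)) {
    stop("labels must be a string over {H, E, C}", call. = FALSE)
  }
  structure(list(labels = labels, provenance = provenance),
            class = "ss_assignment")
}

#' @export
print.ss_assignment <- function(x, ...) {
  tup <- label_tuple(x$labels)
  cat(sprintf("Secondary-structure assignment: %d residues, %d H in %d segments, %d E in %d segments\n",
              nchar(x$labels), tup[1], tup[3], tup[2], tup[4]))
  if (!is.null(x$provenance$discrepancy)) {
    cat(sprintf("  discrepancy vs targets: %g\n", x$provenance$discrepancy))
  }
  invisible(x)
}

label_chars <- function(a) {
  if (inherits(a, "ss_assignment")) a <- a$labels
  strsplit(toupper(as.character(a)), "")[[1]]
}

# counts (n_H, n_E, seg_H, seg_E) of a label character vector
label_tuple <- function(labels) {
  if (is.character(labels) && length(labels) == 1L) labels <- strsplit(labels, "")[[1]]
  n <- length(labels)
  is_h <- labels == "H"
  is_e <- labels == "E"
  seg_h <- sum(is_h & !c(FALSE, is_h[-n]))
  seg_e <- sum(is_e & !c(FALSE, is_e[-n]))
  c(n_h = sum(is_h), n_e = sum(is_e), seg_h = seg_h, seg_e = seg_e)
}

# maximal runs of one class: data.frame(start, end, len)
class_runs <- function(labels, cls) {
  r <- rle(labels == cls)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep], len = r$lengths[keep])
}

#' Assignment targets from the spectroscopic estimates
#'
#' Converts deconvolved contents and segment estimates into the integer
#' targets the constrained assignment must hit: residue counts
#' `round(helix_total * n_res)` and `round(strand_total * n_res)` (half away
#' from zero), and the segment counts from [estimate_segments()]. Infeasible
#' combinations (rounded residue counts exceeding `n_res`, segment counts
#' incompatible with residue counts, or unsatisfiable segment packing) are
#' repaired by decrementing the larger offending count, with a warning.
#'
#' @param f A clean [fraction_vector()].
#' @param seg A [estimate_segments()] result (or list with `n_helix`,
#'   `n_strand`).
#' @param n_res Residue count.
#' @return A list of class `assignment_targets`: `n_h_residues`,
#'   `n_e_residues`, `n_h_segments`, `n_e_segments`, `n_res`, `adjusted`.
#' @export
targets_from_vuvcd <- function(f, seg, n_res) {
  tc <- total_contents(f)
  n_res <- as.integer(n_res)
  r_h <- as.integer(round_half_up(tc[["helix"]] * n_res))
  r_e <- as.integer(round_half_up(tc[["strand"]] * n_res))
  k_h <- as.integer(seg$n_helix)
  k_e <- as.integer(seg$n_strand)
  adjusted <- FALSE
  while (r_h + r_e > n_res) {
    if (r_h >= r_e) r_h <- r_h - 1L else r_e <- r_e - 1L
    adjusted <- TRUE
  }
  if (k_h > r_h) { k_h <- r_h; adjusted <- TRUE }
  if (k_e > r_e) { k_e <- r_e; adjusted <- TRUE }
  if (r_h > 0 && k_h == 0) { k_h <- 1L; adjusted <- TRUE }
  if (r_e > 0 && k_e == 0) { k_e <- 1L; adjusted <- TRUE }
  if (r_h == 0 && k_h > 0) { k_h <- 0L; adjusted <- TRUE }
  if (r_e == 0 && k_e > 0) { k_e <- 0L; adjusted <- TRUE }
  while (!is_feasible_tuple(r_h, r_e, k_h, k_e, n_res)) {
    if (k_h >= k_e && k_h > 1L) k_h <- k_h - 1L
    else if (k_e > 1L) k_e <- k_e - 1L
    else break
    adjusted <- TRUE
  }
  if (adjusted) {
    warning("assignment targets were adjusted for feasibility", call. = FALSE)
  }
  structure(list(n_h_residues = r_h, n_e_residues = r_e,
                 n_h_segments = k_h, n_e_segments = k_e,
                 n_res = n_res, adjusted = adjusted),
            class = "assignment_targets")
}

# Can a labeling of length n realize exactly this tuple?
# Same-class segments need a separator; interleaving the two classes leaves
# max(0, |k_h - k_e| - 1) forced single-C separators.
is_feasible_tuple <- function(r_h, r_e, k_h, k_e, n) {
  if (any(c(r_h, r_e, k_h, k_e) < 0)) return(FALSE)
  if ((r_h > 0) != (k_h > 0)) return(FALSE)
  if ((r_e > 0) != (k_e > 0)) return(FALSE)
  if (k_h > r_h || k_e > r_e) return(FALSE)
  sep <- max(0L, max(k_h, k_e) - min(k_h, k_e) - 1L)
  r_h + r_e + sep <= n
}

#' Discrepancy between an assignment and its targets
#'
#' \deqn{|n_H - \hat n_H| + |n_E - \hat n_E| +
#'   \lambda_{seg} (|s_H - \hat s_H| + |s_E - \hat s_E|)}
#' where hats are targets, `n` residue counts and `s` maximal-run counts.
#'
#' @param a An [ss_assignment()] or label string.
#' @param t An [assignment_targets()].
#' @param lambda_seg Segment-mismatch weight (default 1).
#' @return A single non-negative number.
#' @export
discrepancy <- function(a, t, lambda_seg = 1) {
  labels <- label_chars(a)
  if (length(labels) != t$n_res) {
    stop("assignment length does not match targets' n_res", call. = FALSE)
  }
  tup <- label_tuple(labels)
  discrepancy_tuple(tup, t, lambda_seg)
}

discrepancy_tuple <- function(tup, t, lambda_seg) {
  abs(tup[[1]] - t$n_h_residues) + abs(tup[[2]] - t$n_e_residues) +
    lambda_seg * (abs(tup[[3]] - t$n_h_segments) +
                    abs(tup[[4]] - t$n_e_segments))
}

#' Content- and segment-constrained secondary-structure assignment
#'
#' Chooses per-residue H/E/C labels so that the total numbers of helix and
#' strand residues, and the numbers of helix and strand segments, match the
#' spectroscopically derived targets, guided by per-residue propensity
#' scores.
#'
#' \strong{Phase 1 (greedy ranking).} Residues are labelled H (resp. E) in
#' descending order of `h_score` (resp. `e_score`) until the residue targets
#' are met. The two rankings are merged: a residue claimed by both classes
#' goes to the class giving it the higher score, and the losing class takes
#' its next-ranked unlabelled residue. Ties break to the lower sequence
#' index, then to H before E.
#'
#' \strong{Phase 2 (segment reconciliation).} While a class has more
#' segments than targeted, the two closest same-class segments are merged by
#' relabelling the (all-C) gap, or, when merging is not acceptable, the
#' segment with the lowest total score is deleted; while it has fewer, the
#' longest segment is split at its lowest-scoring interior residue. After
#' each segment operation, residue counts are rebalanced by trimming the
#' lowest-scoring segment-end residues or extending segments at their
#' best-scoring flanking C. Every compound move must not worsen the
#' discrepancy; the search stops at discrepancy 0, when no acceptable move
#' remains, or after `max_moves` moves.
#'
#' \strong{Phase 3 (minimal-difference fallback).} If the labelling is still
#' off target, the discrepancy-optimal achievable count tuple is computed
#' from the exact feasibility characterization of `{H,E,C}` strings, and a
#' labelling realizing it is constructed; the better of the two labellings
#' (ties favour the score-informed search result) is returned. The result's
#' discrepancy therefore always equals the minimum achievable discrepancy,
#' and feasible targets are always met exactly.
#'
#' @param p A [propensity_profile()].
#' @param t An [assignment_targets()] (length must equal the profile's).
#' @param config An [assign_config()].
#' @return An [ss_assignment()]; `provenance` records the targets, the
#'   achieved discrepancy, and which phase produced the result.
#' @export
constrained_assign <- function(p, t, config = assign_config()) {
  stopifnot(inherits(p, "propensity_profile"))
  n <- p$n_res
  if (n != t$n_res) {
    stop("profile length does not match targets' n_res", call. = FALSE)
  }
  lambda <- config$lambda_seg
  max_moves <- config$max_moves %||% (10L * n)

  labels <- greedy_phase1(p, t)
  d1 <- discrepancy_tuple(label_tuple(labels), t, lambda)

  best <- labels
  best_d <- d1
  if (best_d > 0) {
    res <- reconcile_segments(labels, p, t, lambda, max_moves)
    if (res$disc <= best_d) { best <- res$labels; best_d <- res$disc }
  }
  phase <- if (best_d == d1) "greedy" else "reconciled"

  if (best_d > 0) {
    opt <- best_achievable_tuple(t, n, lambda)
    if (opt$disc < best_d) {
      built <- construct_labeling(opt$tuple, n)
      bd <- discrepancy_tuple(label_tuple(built), t, lambda)
      if (bd < best_d) {
        best <- built
        best_d <- bd
        phase <- "constructed"
      }
    }
  }

  ss_assignment(paste(best, collapse = ""),
                provenance = list(targets = unclass(t)[1:5],
                                  discrepancy = best_d,
                                  phase1_discrepancy = d1,
                                  method = phase,
                                  lambda_seg = lambda))
}

greedy_phase1 <- function(p, t) {
  n <- p$n_res
  cand <- data.frame(
    idx = rep(seq_len(n), 2L),
    cls = rep(c("H", "E"), each = n),
    score = c(p$h_score, p$e_score)
  )
  # descending score; ties: lower index, then H before E
  ord <- order(-cand$score, cand$idx, cand$cls)
  cand <- cand[ord, ]
  labels <- rep("C", n)
  need_h <- t$n_h_residues
  need_e <- t$n_e_residues
  for (i in seq_len(nrow(cand))) {
    if (need_h == 0L && need_e == 0L) break
    ix <- cand$idx[i]
    if (labels[ix] != "C") next
    if (cand$cls[i] == "H") {
      if (need_h > 0L) { labels[ix] <- "H"; need_h <- need_h - 1L }
    } else if (need_e > 0L) { labels[ix] <- "E"; need_e <- need_e - 1L }
  }
  labels
}

# one class's score vector
cls_score <- function(p, cls) if (cls == "H") p$h_score else p$e_score

reconcile_segments <- function(labels, p, t, lambda, max_moves) {
  cur_d <- discrepancy_tuple(label_tuple(labels), t, lambda)
  moves <- 0L
  repeat {
    if (cur_d == 0 || moves >= max_moves) break
    improved <- FALSE
    for (cls in c("H", "E")) {
      target_k <- if (cls == "H") t$n_h_segments else t$n_e_segments
      runs <- class_runs(labels, cls)
      k <- nrow(runs)
      cand <- NULL
      if (k > target_k) {
        cand <- c(merge_candidates(labels, runs, cls, p),
                  delete_candidates(labels, runs, cls, p))
      } else if (k < target_k) {
        cand <- split_candidates(labels, runs, cls, p)
      }
      if (is.null(cand) || length(cand) == 0L) next
      for (new_labels in cand) {
        new_labels <- rebalance_residues(new_labels, p, t)
        nd <- discrepancy_tuple(label_tuple(new_labels), t, lambda)
        if (nd < cur_d) {
          labels <- new_labels
          cur_d <- nd
          improved <- TRUE
          moves <- moves + 1L
          break
        }
      }
      if (improved) break
    }
    if (!improved) {
      # final residue rebalance may still help when segment counts are right
      new_labels <- rebalance_residues(labels, p, t)
      nd <- discrepancy_tuple(label_tuple(new_labels), t, lambda)
      if (nd < cur_d) { labels <- new_labels; cur_d <- nd } else break
    }
  }
  list(labels = labels, disc = cur_d)
}

# candidate merges: relabel an all-C gap between two same-class runs,
# closest gaps first
merge_candidates <- function(labels, runs, cls, p) {
  if (nrow(runs) < 2L) return(list())
  gaps <- data.frame(
    from = runs$end[-nrow(runs)] + 1L,
    to = runs$start[-1] - 1L
  )
  gaps$len <- gaps$to - gaps$from + 1L
  ok <- vapply(seq_len(nrow(gaps)), function(i) {
    all(labels[gaps$from[i]:gaps$to[i]] == "C")
  }, logical(1))
  gaps <- gaps[ok, , drop = FALSE]
  gaps <- gaps[order(gaps$len, gaps$from), , drop = FALSE]
  lapply(seq_len(nrow(gaps)), function(i) {
    l <- labels
    l[gaps$from[i]:gaps$to[i]] <- cls
    l
  })
}

# candidate deletions: lowest-total-score segments first
delete_candidates <- function(labels, runs, cls, p) {
  if (nrow(runs) == 0L) return(list())
  sc <- cls_score(p, cls)
  tot <- vapply(seq_len(nrow(runs)), function(i) {
    sum(sc[runs$start[i]:runs$end[i]])
  }, numeric(1))
  ord <- order(tot, runs$start)
  lapply(ord, function(i) {
    l <- labels
    l[runs$start[i]:runs$end[i]] <- "C"
    l
  })
}

# candidate splits: longest runs first, cut at lowest-score interior residue
split_candidates <- function(labels, runs, cls, p) {
  runs <- runs[runs$len >= 3L, , drop = FALSE]
  if (nrow(runs) == 0L) return(list())
  sc <- cls_score(p, cls)
  runs <- runs[order(-runs$len, runs$start), , drop = FALSE]
  lapply(seq_len(nrow(runs)), function(i) {
    interior <- (runs$start[i] + 1L):(runs$end[i] - 1L)
    cut <- interior[which.min(sc[interior])]
    l <- labels
    l[cut] <- "C"
    l
  })
}

# restore residue counts without changing segment counts: trim worst run-end
# residues (runs of length >= 2) or extend runs at their best flanking C
rebalance_residues <- function(labels, p, t) {
  n <- length(labels)
  for (cls in c("H", "E")) {
    target_r <- if (cls == "H") t$n_h_residues else t$n_e_residues
    sc <- cls_score(p, cls)
    repeat {
      cur_r <- sum(labels == cls)
      if (cur_r == target_r) break
      runs <- class_runs(labels, cls)
      if (cur_r > target_r) {
        ends <- integer(0)
        long <- runs[runs$len >= 2L, , drop = FALSE]
        if (nrow(long) > 0L) ends <- c(long$start, long$end)
        if (length(ends) == 0L) break
        pick <- ends[which.min(sc[ends])]
        labels[pick] <- "C"
      } else {
        # flanking C positions that extend a run without touching another
        # same-class run
        flanks <- integer(0)
        if (nrow(runs) > 0L) {
          left <- runs$start - 1L
          right <- runs$end + 1L
          cand <- c(left, right)
          cand <- cand[cand >= 1L & cand <= n]
          cand <- cand[labels[cand] == "C"]
          safe <- vapply(cand, function(ix) {
            nb <- c(ix - 1L, ix + 1L)
            nb <- nb[nb >= 1L & nb <= n]
            sum(labels[nb] == cls) == 1L
          }, logical(1))
          flanks <- unique(cand[safe])
        }
        if (length(flanks) == 0L) break
        pick <- flanks[which.max(sc[flanks])]
        labels[pick] <- cls
      }
    }
  }
  labels
}

# exact minimization of the discrepancy over achievable count tuples
best_achievable_tuple <- function(t, n, lambda) {
  R_h <- t$n_h_residues; R_e <- t$n_e_residues
  K_h <- t$n_h_segments; K_e <- t$n_e_segments
  best_d <- Inf
  best <- NULL
  for (k_h in 0:n) {
    seg_h_cost <- lambda * abs(k_h - K_h)
    if (seg_h_cost >= best_d) next
    for (k_e in 0:n) {
      seg_cost <- seg_h_cost + lambda * abs(k_e - K_e)
      if (seg_cost >= best_d) next
      sep <- max(0L, max(k_h, k_e) - min(k_h, k_e) - 1L)
      S <- n - sep
      m_h <- k_h; m_e <- k_e # min residues per class (0 iff k = 0)
      if (m_h + m_e > S) next
      u_h <- S - m_e; u_e <- S - m_h
      r_h <- if (k_h == 0L) 0L else min(max(R_h, m_h), u_h)
      r_e <- if (k_e == 0L) 0L else min(max(R_e, m_e), u_e)
      over <- r_h + r_e - S
      if (over > 0L) {
        take_h <- min(over, r_h - m_h)
        r_h <- r_h - take_h
        r_e <- r_e - (over - take_h)
      }
      d <- seg_cost + abs(r_h - R_h) + abs(r_e - R_e)
      if (d < best_d) {
        best_d <- d
        best <- c(r_h = r_h, r_e = r_e, k_h = k_h, k_e = k_e)
        if (best_d == 0) return(list(tuple = best, disc = 0))
      }
    }
  }
  list(tuple = best, disc = best_d)
}

# deterministic labeling realizing an achievable tuple: interleave the
# majority-class runs with minority runs, single-C separators where forced,
# trailing C padding
construct_labeling <- function(tuple, n) {
  r_h <- tuple[["r_h"]]; r_e <- tuple[["r_e"]]
  k_h <- tuple[["k_h"]]; k_e <- tuple[["k_e"]]
  split_len <- function(r, k) {
    if (k == 0L) return(integer(0))
    base <- r %/% k
    extra <- r %% k
    c(rep(base + 1L, extra), rep(base, k - extra))
  }
  if (k_h >= k_e) {
    maj_cls <- "H"; min_cls <- "E"
    maj <- split_len(r_h, k_h); mi <- split_len(r_e, k_e)
  } else {
    maj_cls <- "E"; min_cls <- "H"
    maj <- split_len(r_e, k_e); mi <- split_len(r_h, k_h)
  }
  out <- character(0)
  for (i in seq_along(maj)) {
    out <- c(out, rep(maj_cls, maj[i]))
    if (i <= length(mi)) {
      out <- c(out, rep(min_cls, mi[i]))
    } else if (i < length(maj)) {
      out <- c(out, "C")
    }
  }
  if (length(mi) > length(maj)) { # only when k_maj == 0
    for (i in seq_along(mi)) out <- c(out, rep(min_cls, mi[i]))
  }
  c(out, rep("C", n - length(out)))
}

#' Positions where two assignments differ
#'
#' @param a,b [ss_assignment()]s or label strings of equal length.
#' @param offset Optional residue offset: when the construct carries an
#'   N-terminal tag of `offset` residues, `position - offset` gives the
#'   position in the untagged protein's numbering (reported in an extra
#'   column).
#' @return A data frame with columns `position` (1-based along the full
#'   construct), `label_a`, `label_b`, and `protein_position` if `offset`
#'   is non-zero. Zero rows when the assignments agree everywhere.
#' @export
diff_assignments <- function(a, b, offset = 0L) {
  la <- label_chars(a)
  lb <- label_chars(b)
  if (length(la) != length(lb)) {
    stop("assignments have different lengths", call. = FALSE)
  }
  pos <- which(la != lb)
  out <- data.frame(position = pos, label_a = la[pos], label_b = lb[pos],
                    stringsAsFactors = FALSE)
  if (offset != 0L) out$protein_position <- out$position - as.integer(offset)
  out
}

#' Segment and residue counts within a region
#'
#' Counts the maximal H and E runs that intersect a 1-based inclusive
#' interval (a run clipped at a boundary counts once), and the H/E residue
#' counts inside the interval.
#'
#' @param a An [ss_assignment()] or label string.
#' @param range Length-2 integer vector `c(from, to)`, 1-based inclusive.
#' @return A list: `helix_segments`, `strand_segments`, `n_h_residues`,
#'   `n_e_residues`.
#' @examples
#' region_summary("CCHHHHCEEC", c(3, 8))
#' @export
region_summary <- function(a, range) {
  labels <- label_chars(a)
  n <- length(labels)
  from <- as.integer(range[1]); to <- as.integer(range[2])
  if (from < 1L || to > n || from > to) {
    stop(sprintf("invalid range [%d, %d] for a %d-residue assignment",
                 from, to, n), call. = FALSE)
  }
  count_intersecting <- function(cls) {
    runs <- class_runs(labels, cls)
    sum(runs$start <= to & runs$end >= from)
  }
  seg <- labels[from:to]
  list(helix_segments = count_intersecting("H"),
       strand_segments = count_intersecting("E"),
       n_h_residues = sum(seg == "H"),
       n_e_residues = sum(seg == "E"))
}

#' Write an assignment as a secondary-structure string file and TSV
#'
#' @param a An [ss_assignment()].
#' @param sequence Optional amino-acid sequence (same length) for the TSV's
#'   residue column.
#' @param path Base path: `<path>.ss.fasta` (FASTA-like string) and
#'   `<path>.ss.tsv` (position, residue, label) are written.
#' @param name Record name for the FASTA-like file.
#' @return Invisibly, the two paths.
#' @export
write_assignment <- function(a, path, sequence = NULL, name = "assignment") {
  labels <- label_chars(a)
  fa <- paste0(path, ".ss.fasta")
  writeLines(c(paste0(">", name), paste(labels, collapse = "")), fa)
  tsv <- paste0(path, ".ss.tsv")
  aa <- if (is.null(sequence)) rep(".", length(labels)) else
    strsplit(toupper(sequence), "")[[1]]
  utils::write.table(
    data.frame(position = seq_along(labels), residue = aa, label = labels),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fa, tsv))
}
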