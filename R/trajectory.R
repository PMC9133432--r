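#' Simulate a multi-replicate MD trajectory between two templates
#'
#' Each frame is a convex combination of the active and inactive template
#' coordinates (`w * active + (1 - w) * inactive`) plus independent
#' Gaussian coordinate noise. Frame timestamps are uniform over
#' `[0, total_ns]`. The two templates must share an identical atom roster.
#' Coordinates are stored per replicate as an atoms x 3 x frames array, so
#' production-scale replicates (thousands of frames) stay cheap; frames
#' materialise as [structure_model()]s on demand.
#'
#' @param template_active,template_inactive [structure_model()]s sharing
#'   one roster (see [simulate_receptor_templates()] or
#'   [simulate_structure_pair()]).
#' @param n_replicates Number of replicates (7 active / 2 inactive in the
#'   emulated study design).
#' @param n_frames Frames per replicate.
#' @param mixing Per-frame weight path: scalar or numeric vector of length
#'   `n_frames` in `[0, 1]`; 1 = fully active.
#' @param noise_sd Gaussian coordinate noise (Angstrom).
#' @param seed Integer seed; output is bitwise-reproducible.
#' @param total_ns Simulated time span (default 500 ns).
#' @param genotype Condition label (`"WT"` or a mutant id).
#' @param state Simulated activation state label.
#' @return An object of class `trajectory_sample`.
#' @export
simulate_trajectory <- function(template_active, template_inactive,
                                n_replicates = 7, n_frames = 11,
                                mixing = 1, noise_sd = 0, seed = 1L,
                                total_ns = 500, genotype = "WT",
                                state = c("active", "inactive")) {
  state <- match.arg(state)
  stopifnot(inherits(template_active, "structure_model"),
            inherits(template_inactive, "structure_model"))
  roster_cols <- c("chain", "residue_index", "residue_name", "atom_name",
                   "generic_number")
  ra <- as.data.frame(as_tibble(template_active))[, roster_cols]
  ri <- as.data.frame(as_tibble(template_inactive))[, roster_cols]
  if (!isTRUE(all.equal(ra, ri, check.attributes = FALSE))) {
    abort("templates do not share an identical atom roster")
  }
  w <- rep_len(mixing, n_frames)
  if (any(w < 0 | w > 1)) abort("mixing weights must lie in [0, 1]")
  ca <- as.matrix(as_tibble(template_active)[, c("x", "y", "z")])
  ci <- as.matrix(as_tibble(template_inactive)[, c("x", "y", "z")])
  na <- nrow(ca)
  times <- seq(0, total_ns, length.out = n_frames)
  with_seed(seed, {
    replicates <- lapply(seq_len(n_replicates), function(r) {
      arr <- array(0, dim = c(na, 3, n_frames))
      for (k in seq_len(n_frames)) {
        frame <- w[k] * ca + (1 - w[k]) * ci
        if (noise_sd > 0) {
          frame <- frame + matrix(rnorm(na * 3, sd = noise_sd), ncol = 3)
        }
        arr[, , k] <- frame
      }
      arr
    })
    structure(
      list(
        genotype = genotype,
        state = state,
        roster = as_tibble(template_active)[, c(roster_cols, "element")],
        times = times,
        replicates = replicates
      ),
      class = "trajectory_sample"
    )
  })
}

#' @export
print.trajectory_sample <- function(x, ...) {
  cat("<trajectory_sample> ", x$genotype, "/", x$state, ": ",
      length(x$replicates), " replicate(s) x ", length(x$times),
      " frames (", total_frames(x), " total), 0-",
      max(x$times), " ns\n", sep = "")
  invisible(x)
}

#' Total number of frames across all replicates
#' @param traj A `trajectory_sample`.
#' @return Integer frame count.
#' @export
total_frames <- function(traj) {
  stopifnot(inherits(traj, "trajectory_sample"))
  sum(vapply(traj$replicates, function(a) dim(a)[3], numeric(1)))
}

#' Materialise one trajectory frame as a structure model
#' @param traj A `trajectory_sample`.
#' @param replicate Replicate number.
#' @param index Frame index within the replicate.
#' @return A [structure_model()].
#' @export
trajectory_frame <- function(traj, replicate, index) {
  stopifnot(inherits(traj, "trajectory_sample"))
  arr <- traj$replicates[[replicate]]
  atoms <- traj$roster
  atoms$x <- arr[, 1, index]
  atoms$y <- arr[, 2, index]
  atoms$z <- arr[, 3, index]
  structure_model(
    atoms,
    structure_id = sprintf("%s_%s_r%d_f%d", traj$genotype, traj$state,
                           replicate, index),
    state = traj$state
  )
}

#' Sample frames at regular time intervals
#'
#' Selects, per replicate, the frame nearest to each target time on the
#' inclusive grid `start_ns, start_ns + step_ns, ..., end_ns`, giving
#' `(end_ns - start_ns) / step_ns + 1` frames per replicate (11 for the
#' default 0-500 ns at 50 ns steps).
#'
#' @param traj A `trajectory_sample`.
#' @param start_ns,end_ns,step_ns Sampling grid in nanoseconds.
#' @return Tibble with `replicate`, `target_ns`, `time_ns` (actual frame
#'   time) and a `frame` list-column of [structure_model()]s.
#' @export
sample_frames <- function(traj, start_ns = 0, end_ns = 500, step_ns = 50) {
  stopifnot(inherits(traj, "trajectory_sample"))
  if (max(traj$times) < end_ns) {
    abort(paste0("trajectory spans only ", max(traj$times),
                 " ns, shorter than end_ns = ", end_ns))
  }
  targets <- seq(start_ns, end_ns, by = step_ns)
  out <- lapply(seq_along(traj$replicates), function(r) {
    idx <- vapply(targets, function(t) which.min(abs(traj$times - t)),
                  integer(1))
    tibble(
      replicate = r,
      target_ns = targets,
      time_ns = traj$times[idx],
      frame = lapply(idx, function(i) trajectory_frame(traj, r, i))
    )
  })
  bind_rows(out)
}

frame_list <- function(frames) {
  if (is_tibble(frames) && "frame" %in% names(frames)) return(frames$frame)
  if (inherits(frames, "structure_model")) return(list(frames))
  stopifnot(is.list(frames))
  frames
}

#' WT-vs-mutant contact-change test over trajectory frames
#'
#' Computes per-frame RRCS for both frame sets, then tests each residue
#' pair with a two-sided two-sample t-test over the per-frame scores
#' (a frame without the contact contributes zero). Pairs that never score
#' on either side are skipped. Pairs with p below `alpha` are retained
#' with the mutant-minus-WT mean change and its sign.
#'
#' @param wt_frames,mut_frames Lists of [structure_model()]s (or tibbles
#'   from [sample_frames()]); at least 2 frames per side.
#' @param alpha Significance level (default 0.05; the stricter 0.01
#'   reporting filter can be applied downstream via the returned
#'   p-values).
#' @param var_equal Student (default) vs Welch t-test.
#' @param ... RRCS parameters passed to [compute_rrcs()].
#' @return A [contact_network()] with `delta`, `p_value` and `sign`.
#' @export
contact_change_test <- function(wt_frames, mut_frames, alpha = 0.05,
                                var_equal = TRUE, ...) {
  wt <- frame_list(wt_frames)
  mut <- frame_list(mut_frames)
  if (length(wt) < 2 || length(mut) < 2) {
    abort("need at least 2 frames per side for a contact-change test")
  }
  nets_wt <- lapply(wt, compute_rrcs, ...)
  nets_mut <- lapply(mut, compute_rrcs, ...)
  all_edges <- distinct(bind_rows(lapply(c(nets_wt, nets_mut), function(n) {
    tibble(source = n$source, target = n$target)
  })))
  if (nrow(all_edges) == 0) {
    return(empty_network(kind = "contact_change",
                         value_cols = c("delta", "p_value", "sign")))
  }
  keys <- paste(all_edges$source, all_edges$target, sep = "|")
  fill <- function(nets) {
    vapply(nets, function(n) {
      v <- setNames(rep(0, length(keys)), keys)
      v[edge_keys(n)] <- n$score
      v
    }, numeric(length(keys)))
  }
  vw <- matrix(fill(nets_wt), nrow = length(keys))
  vm <- matrix(fill(nets_mut), nrow = length(keys))
  res <- lapply(seq_along(keys), function(e) {
    x <- vw[e, ]
    y <- vm[e, ]
    if (all(x == 0) && all(y == 0)) return(NULL)
    tibble(source = all_edges$source[e], target = all_edges$target[e],
           delta = mean(y) - mean(x),
           p_value = safe_t_test(y, x, var_equal = var_equal))
  })
  res <- bind_rows(res)
  if (nrow(res) == 0) {
    return(empty_network(kind = "contact_change",
                         value_cols = c("delta", "p_value", "sign")))
  }
  res <- res[!is.na(res$p_value) & res$p_value < alpha, ]
  res$sign <- sign(res$delta)
  contact_network(res, kind = "contact_change")
}

#' Contact changes common to every mutant
#'
#' Intersects significant contact-change networks across mutational
#' states: an edge survives only if present in every input network. The
#' per-mutant signs are recorded side by side.
#'
#' @param per_mutant_networks Named (or unnamed) list of >= 2
#'   [contact_network()]s from [contact_change_test()].
#' @return A [contact_network()] with one `sign_*` column per input.
#' @export
intersect_common_changes <- function(per_mutant_networks) {
  stopifnot(length(per_mutant_networks) >= 2)
  nms <- names(per_mutant_networks) %||%
    paste0("mutant", seq_along(per_mutant_networks))
  nms[nms == ""] <- paste0("mutant", which(nms == ""))
  tabs <- lapply(seq_along(per_mutant_networks), function(i) {
    n <- per_mutant_networks[[i]]
    out <- tibble(source = n$source, target = n$target)
    out[[paste0("sign_", nms[i])]] <-
      if ("sign" %in% names(n)) n$sign else sign(n$delta)
    out
  })
  merged <- Reduce(function(a, b) inner_join(a, b, by = c("source", "target")),
                   tabs)
  contact_network(merged, kind = "common_change")
}

#' GPCRdb activation-state classification of a frame
#'
#' Computes the activation metric d(2x41, 6x38) - d(3x44, 7x52) from the
#' CA atoms of the four marker residues and classifies the conformation:
#' active above 7.15 Angstrom, inactive below 2, intermediate in between
#' (both inequalities strict, so the boundary values themselves are
#' intermediate).
#'
#' @param frame A [structure_model()] with the four marker residues
#'   annotated and carrying CA atoms.
#' @param markers Generic numbers of the markers, ordered as the two
#'   distance pairs `(a1, a2, b1, b2)` with metric `d(a1,a2) - d(b1,b2)`.
#' @param active_min,inactive_max Classification cutoffs in Angstrom.
#' @return One-row tibble with `gpcrdb_distance` and `call`.
#' @export
classify_state <- function(frame, markers = c("2x41", "6x38", "3x44", "7x52"),
                           active_min = 7.15, inactive_max = 2) {
  stopifnot(inherits(frame, "structure_model"), length(markers) == 4)
  atoms <- as_tibble(frame)
  ca <- atoms[atoms$atom_name == "CA" & !is.na(atoms$generic_number), ]
  idx <- match(markers, ca$generic_number)
  if (anyNA(idx)) {
    abort(paste0("missing marker residue (CA): ",
                 paste(markers[is.na(idx)], collapse = ", ")))
  }
  xyz <- as.matrix(ca[idx, c("x", "y", "z")])
  d <- function(i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  metric <- d(1, 2) - d(3, 4)
  call <- if (metric > active_min) "active" else
    if (metric < inactive_max) "inactive" else "intermediate"
  tibble(gpcrdb_distance = metric, call = call)
}

#' Classify every frame of a sampled trajectory
#'
#' @param frames Tibble from [sample_frames()] or a list of frames.
#' @param ... Passed to [classify_state()].
#' @return Tibble of state calls (class `state_calls`), one row per frame.
#' @export
classify_states <- function(frames, ...) {
  fl <- frame_list(frames)
  out <- bind_rows(lapply(fl, classify_state, ...))
  if (is_tibble(frames) && "replicate" %in% names(frames)) {
    out <- bind_cols(frames[, intersect(c("replicate", "time_ns"),
                                        names(frames))], out)
  }
  structure(out, class = c("state_calls", class(out)))
}
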