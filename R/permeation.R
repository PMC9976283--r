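#' Define the channel span used for permeation counting
#'
#' The span is the axial interval an ion must fully traverse for a crossing
#' to count; it should bracket the selectivity-filter region. An optional
#' lateral radius restricts "inside" to a cylinder around the pore axis.
#'
#' @param z_lower,z_upper axial bounds in Angstrom, \code{z_lower < z_upper}
#' @param lateral_radius optional cylinder radius (Angstrom)
#' @return object of class \code{channel_span}
#' @export
channel_span <- function(z_lower, z_upper, lateral_radius = NULL) {
  if (!(z_lower < z_upper)) stop("z_lower must be < z_upper")
  if (!is.null(lateral_radius) && lateral_radius <= 0)
    stop("lateral_radius must be positive")
  structure(list(z_lower = z_lower, z_upper = z_upper,
                 lateral_radius = lateral_radius), class = "channel_span")
}

# per-step wrap detection: TRUE where |dz| > box_z/2 (the ion was recycled
# through the periodic boundary, not moved physically across the box)
.wrap_jumps <- function(z, box_z) {
  if (length(z) < 2) return(logical(0))
  abs(diff(z)) > box_z / 2
}

# continuous (unwrapped) axial coordinate by minimum-image accumulation
.unwrap_z <- function(z, box_z) {
  if (length(z) < 2) return(z)
  dz <- diff(z)
  dz <- dz - box_z * round(dz / box_z)
  c(z[1], z[1] + cumsum(dz))
}

#' Detect ion permeation events through a channel span
#'
#' Uses a three-state hysteresis detector (below / inside / above the span):
#' an outward event is recorded only when an ion's state passes
#' below -> inside -> above, an inward event for the reverse order.
#' Excursions that re-exit on the entry side count nothing. Periodic jumps
#' (|dz| > box_z/2 between frames, the reservoir-recycling signature) never
#' generate state transitions through the span interior. Direct single-frame
#' hops across the whole span that are not periodic jumps are treated as a
#' physical traversal. An event is attributed to the frame where the ion
#' first appears on the far side.
#'
#' @param traj trajectory
#' @param span [channel_span()]
#' @param ion_selection roles to treat as permeant ions (default "ion"), or
#'   an integer vector of atom table row indices
#' @param check_step if TRUE, warn when a non-wrap step exceeds box_z/4
#'   (time resolution likely too coarse for reliable unwrapping)
#' @return data.frame with columns ion_id, completion_frame, direction
#'   ("outward" or "inward"); class \code{permeation_events}
#' @export
detect_events <- function(traj, span, ion_selection = "ion",
                          check_step = TRUE) {
  stopifnot(inherits(traj, "trajectory"), inherits(span, "channel_span"))
  idx <- if (is.numeric(ion_selection)) as.integer(ion_selection)
         else select_atoms(traj, ion_selection)
  if (!length(idx)) stop("empty ion selection")
  box_z <- traj$box[, 3]
  if (any(span$z_upper - span$z_lower >= box_z))
    stop("channel span is wider than the box along z")
  nf <- n_frames(traj)
  out <- list()
  for (ii in idx) {
    z <- traj$coords[, ii, 3]
    st <- ifelse(z < span$z_lower, 1L, ifelse(z > span$z_upper, 3L, 2L))
    if (!is.null(span$lateral_radius)) {
      r <- sqrt(traj$coords[, ii, 1]^2 + traj$coords[, ii, 2]^2)
      # outside the cylinder an ion is never "inside"; assign it to the
      # nearer axial side so bulk excursions around the pore do not arm
      # the detector
      lateral_out <- st == 2L & r > span$lateral_radius
      mid <- (span$z_lower + span$z_upper) / 2
      st[lateral_out] <- ifelse(z[lateral_out] < mid, 1L, 3L)
    }
    wrap <- .wrap_jumps(z, box_z[1])
    if (check_step && nf > 1) {
      dz <- abs(diff(z))
      big <- dz > box_z[1] / 4 & !wrap
      if (any(big))
        warning("ion ", traj$atoms$atom_id[ii], ": ", sum(big),
                " step(s) exceed box_z/4; frame spacing may be too coarse")
    }
    armed <- 0L  # 1 = entered from below, 3 = entered from above
    state <- st[1]
    ev_frame <- integer(0); ev_dir <- character(0)
    for (f in 2:max(nf, 2)) {
      if (nf < 2) break
      s_new <- st[f]
      if (s_new == state) next
      if (wrap[f - 1]) {
        # periodic recycling: reset, adopt the new side without arming
        armed <- 0L
        state <- s_new
        next
      }
      if (state != 2L && s_new == 2L) {
        armed <- state
      } else if (state == 2L && s_new != 2L) {
        if (armed != 0L && s_new != armed) {
          ev_frame <- c(ev_frame, f)
          ev_dir <- c(ev_dir, if (s_new == 3L) "outward" else "inward")
        }
        armed <- 0L
      } else if (state != 2L && s_new != 2L) {
        # direct hop across the span within one (non-wrap) step
        ev_frame <- c(ev_frame, f)
        ev_dir <- c(ev_dir, if (s_new == 3L) "outward" else "inward")
        armed <- 0L
      }
      state <- s_new
    }
    if (length(ev_frame))
      out[[length(out) + 1L]] <- data.frame(
        ion_id = traj$atoms$atom_id[ii], completion_frame = ev_frame,
        direction = ev_dir, stringsAsFactors = FALSE)
  }
  ev <- if (length(out)) do.call(rbind, out) else
    data.frame(ion_id = integer(), completion_frame = integer(),
               direction = character(), stringsAsFactors = FALSE)
  ev <- ev[order(ev$completion_frame, ev$ion_id), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("permeation_events", "data.frame")
  ev
}

#' Convert permeation events to current and conductance
#'
#' Current is the net transferred charge per unit time,
#' I = n_net * q * e / t with n_net = outward - inward event counts (set
#' \code{counting = "outward"} to use outward events only); conductance is
#' G = I / V, reported in picosiemens.
#'
#' @param events \code{permeation_events} data.frame from [detect_events()]
#' @param sim_time total simulated time in ns
#' @param voltage transmembrane voltage in V (nonzero)
#' @param ion_charge ion charge in units of e (default 2, divalent calcium)
#' @param counting "net" (outward - inward) or "outward"
#' @return object of class \code{conductance_estimate}: list with n_events
#'   (signed count used), n_outward, n_inward, sim_time, voltage, ion_charge,
#'   current (A) and conductance (pS)
#' @export
conductance <- function(events, sim_time, voltage, ion_charge = 2,
                        counting = c("net", "outward")) {
  counting <- match.arg(counting)
  if (sim_time <= 0) stop("sim_time must be positive")
  if (voltage == 0) stop("conductance undefined at zero voltage")
  if (is.numeric(events)) {
    n_out <- as.integer(events); n_in <- 0L
  } else {
    n_out <- sum(events$direction == "outward")
    n_in <- sum(events$direction == "inward")
  }
  n <- if (counting == "net") n_out - n_in else n_out
  e_C <- permeonics_constants()$elementary_charge
  current <- n * ion_charge * e_C / (sim_time * 1e-9)
  structure(list(n_events = n, n_outward = n_out, n_inward = n_in,
                 sim_time = sim_time, voltage = voltage,
                 ion_charge = ion_charge, counting = counting,
                 current = current, conductance_pS = current / voltage * 1e12),
            class = "conductance_estimate")
}

#' @export
print.conductance_estimate <- function(x, ...) {
  cat(sprintf("conductance: %.4g pS (%d events [%s], q = %g e, t = %g ns, V = %g V)\n",
              x$conductance_pS, x$n_events, x$counting, x$ion_charge,
              x$sim_time, x$voltage))
  invisible(x)
}

#' Mean and sample standard deviation of per-replica conductances
#'
#' @param per_replica numeric vector of conductances (pS), one per
#'   independent simulation run
#' @return list(mean, sd, n); sd is NA for a single replica (n-1 denominator)
#' @export
replicate_stats <- function(per_replica) {
  if (!length(per_replica)) stop("no replicas supplied")
  list(mean = mean(per_replica),
       sd = if (length(per_replica) >= 2) stats::sd(per_replica) else NA_real_,
       n = length(per_replica))
}

#' Per-ion axial traces for plotting
#'
#' Returns unwrapped z(t) for each selected ion, optionally restricted to a
#' window around the channel span (bulk segments outside the window are
#' dropped).
#'
#' @param traj trajectory
#' @param span [channel_span()] used to center the window; NULL disables
#'   filtering
#' @param ion_selection roles or atom row indices
#' @param window half-width (Angstrom) of the reporting window around the
#'   span (applied to the wrapped coordinate); Inf keeps everything
#' @return data.frame (ion_id, frame, time, z, z_unwrapped)
#' @export
trace_table <- function(traj, span = NULL, ion_selection = "ion",
                        window = Inf) {
  idx <- if (is.numeric(ion_selection)) as.integer(ion_selection)
         else select_atoms(traj, ion_selection)
  if (!length(idx)) stop("empty ion selection")
  box_z <- traj$box[1, 3]
  res <- lapply(idx, function(ii) {
    z <- traj$coords[, ii, 3]
    keep <- rep(TRUE, length(z))
    if (!is.null(span) && is.finite(window))
      keep <- z >= span$z_lower - window & z <= span$z_upper + window
    data.frame(ion_id = traj$atoms$atom_id[ii], frame = which(keep),
               time = traj$times[keep], z = z[keep],
               z_unwrapped = .unwrap_z(z, box_z)[keep])
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
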