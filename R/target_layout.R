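#' Center-out target layouts
#'
#' Deterministic target configurations of the instructed-delay reaching
#' task, in Cartesian cm with the origin at the central touch point:
#'
#' * `"ring"`: targets evenly spaced on a circle of radius 8 cm starting
#'   at angle 0 (24 targets for subject `"J"`, 36 for `"R"`).
#' * `"horizontal"` / `"vertical"`: 24 targets on a line through the
#'   origin, 12 on each side, spaced 1 cm apart (distances 1..12 cm).
#' * `"rings3"`: three concentric rings of radii 4, 8 and 12 cm with 16
#'   evenly spaced targets each (22.5 degree spacing), 48 targets total.
#'
#' Condition ids are contiguous from 0 in construction order.
#'
#' @param name one of `"ring"`, `"horizontal"`, `"vertical"`, `"rings3"`.
#' @param subject `"J"` or `"R"` (only the ring target count differs).
#' @return an object of class `target_layout`: a list with `name`,
#'   `subject`, `targets` (data.frame of `condition_id`, `x`, `y`) and
#'   `ring_radii` (cm; empty for line layouts).
#' @examples
#' lay <- make_target_layout("rings3", "J")
#' nrow(lay$targets)   # 48
#' lay$ring_radii      # 4 8 12
#' @export
make_target_layout <- function(name = TASKS, subject = c("J", "R")) {
  name <- match.arg(name)
  subject <- match.arg(subject)
  if (name == "ring") {
    n <- if (subject == "J") 24L else 36L
    th <- 2 * pi * (seq_len(n) - 1) / n
    targets <- data.frame(condition_id = seq_len(n) - 1L,
                          x = 8 * cos(th), y = 8 * sin(th))
    radii <- 8
  } else if (name == "rings3") {
    radii <- c(4, 8, 12)
    th <- 2 * pi * (0:15) / 16
    targets <- do.call(rbind, lapply(seq_along(radii), function(i) {
      data.frame(condition_id = 16L * (i - 1L) + 0:15,
                 x = radii[i] * cos(th), y = radii[i] * sin(th))
    }))
  } else {
    d <- c(seq(-12, -1), seq(1, 12))
    targets <- if (name == "horizontal") {
      data.frame(condition_id = seq_along(d) - 1L, x = d, y = 0)
    } else {
      data.frame(condition_id = seq_along(d) - 1L, x = 0, y = d)
    }
    radii <- numeric(0)
  }
  structure(list(name = name, subject = subject, targets = targets,
                 ring_radii = radii),
            class = "target_layout")
}

#' @export
print.target_layout <- function(x, ...) {
  cat(sprintf("<target_layout '%s' subject %s: %d targets%s>\n",
              x$name, x$subject, nrow(x$targets),
              if (length(x$ring_radii))
                paste0(", radii ", paste(x$ring_radii, collapse = "/"), " cm")
              else ", line layout"))
  invisible(x)
}

# Distance of each condition's target from the origin, cm.
#' @keywords internal
#' @noRd
target_distance <- function(x, y) sqrt(x^2 + y^2)

# Group distances with a fixed rounding so floating noise cannot split
# a nominal distance into several groups.
#' @keywords internal
#' @noRd
round_distance <- function(d) round(d / 1e-6) * 1e-6
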