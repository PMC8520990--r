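#' Two-segment cochlear input-output function
#'
#' A broken-stick basilar-membrane input-output curve: linear with slope 1
#' (amplified by `gain_db`) below the compression breakpoint, compressive
#' with slope `compression` above it. The two segments meet continuously at
#' the breakpoint, so the curve is strictly increasing for
#' `0 < compression <= 1`.
#'
#' @param gain_db Low-level cochlear gain G in dB (>= 0).
#' @param compression Compressive slope c, dimensionless, in (0, 1].
#' @param breakpoint_db Input level BP in dB SPL where compression begins.
#' @return An object of class `io_function`.
#' @examples
#' io <- io_function(gain_db = 40, compression = 0.2, breakpoint_db = 40)
#' io_output(c(30, 40, 60), io) # 70 80 84
#' @export
io_function <- function(gain_db, compression, breakpoint_db) {
  if (!is.numeric(gain_db) || length(gain_db) != 1 || !is.finite(gain_db) ||
      gain_db < 0) {
    stop_invalid("`gain_db` must be a single finite value >= 0")
  }
  if (!is.numeric(compression) || length(compression) != 1 ||
      !is.finite(compression) || compression <= 0 || compression > 1) {
    stop_invalid("`compression` must be in (0, 1]")
  }
  if (!is.numeric(breakpoint_db) || length(breakpoint_db) != 1 ||
      !is.finite(breakpoint_db)) {
    stop_invalid("`breakpoint_db` must be a single finite level in dB SPL")
  }
  structure(
    list(gain_db = gain_db, compression = compression,
         breakpoint_db = breakpoint_db),
    class = "io_function"
  )
}

#' @export
print.io_function <- function(x, ...) {
  cat(sprintf(
    "<io_function> gain %.1f dB, compression %.2f, breakpoint %.1f dB SPL\n",
    x$gain_db, x$compression, x$breakpoint_db))
  invisible(x)
}

#' Evaluate a cochlear input-output function
#'
#' @param input_db Input level(s) in dB SPL.
#' @param io An [io_function()].
#' @return Place output level(s) in dB.
#' @export
io_output <- function(input_db, io) {
  stopifnot(inherits(io, "io_function"))
  below <- input_db < io$breakpoint_db
  out <- numeric(length(input_db))
  out[below] <- input_db[below] + io$gain_db
  out[!below] <- io$breakpoint_db + io$gain_db +
    io$compression * (input_db[!below] - io$breakpoint_db)
  out
}

#' Invert a cochlear input-output function
#'
#' Closed-form inverse of [io_output()]; exact because the curve is piecewise
#' linear and strictly increasing.
#'
#' @param output_db Place output level(s) in dB.
#' @param io An [io_function()].
#' @return Input level(s) in dB SPL.
#' @export
io_inverse <- function(output_db, io) {
  stopifnot(inherits(io, "io_function"))
  knee_out <- io$breakpoint_db + io$gain_db
  below <- output_db < knee_out
  inp <- numeric(length(output_db))
  inp[below] <- output_db[below] - io$gain_db
  inp[!below] <- io$breakpoint_db +
    (output_db[!below] - knee_out) / io$compression
  inp
}

#' Reduce the low-level gain of an input-output function
#'
#' Models efferent (MOCR) gain reduction: the low-level gain drops by
#' `delta_g` dB while the upper compressive segment is left unchanged, so the
#' breakpoint moves up to `BP + delta_g / (1 - c)`. High-level responses are
#' therefore unaffected, and every input below the original breakpoint loses
#' exactly `delta_g` dB of output. For a fully linear curve (`c = 1`) there is
#' no pivot point; the response below the original breakpoint is simply
#' lowered by `delta_g`.
#'
#' @param io An [io_function()].
#' @param delta_g Gain reduction in dB; must satisfy `0 <= delta_g <= gain_db`.
#' @return A new `io_function` with the reduced gain.
#' @examples
#' io <- io_function(40, 0.2, 40)
#' red <- apply_gain_reduction(io, 10)
#' io_output(30, red) # 60 (was 70)
#' io_output(60, red) # 84 (unchanged)
#' @export
apply_gain_reduction <- function(io, delta_g) {
  stopifnot(inherits(io, "io_function"))
  if (!is.numeric(delta_g) || length(delta_g) != 1 || !is.finite(delta_g) ||
      delta_g < 0 || delta_g > io$gain_db) {
    stop_invalid("`delta_g` must satisfy 0 <= delta_g <= gain_db")
  }
  if (delta_g == 0) return(io)
  if (io$compression < 1) {
    io_function(io$gain_db - delta_g, io$compression,
                io$breakpoint_db + delta_g / (1 - io$compression))
  } else {
    # degenerate linear curve: no pivot exists; lower the low-level segment
    io_function(io$gain_db - delta_g, 1, io$breakpoint_db)
  }
}
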