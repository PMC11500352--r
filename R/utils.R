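#' @importFrom stats median rbeta rbinom rnbinom runif setNames
#' @importFrom utils read.table write.table packageVersion
NULL

BASES <- c("A", "C", "G", "T")

#' The twelve ordered mismatch classes
#'
#' All ordered pairs of distinct bases over {A,C,G,T}, encoded as two-letter
#' strings (reference base followed by observed base). "AG" is the A-to-I
#' editing class; the remaining eleven serve as decoy null classes.
#'
#' @return Character vector of length 12.
#' @export
mismatch_classes <- function() {
  cl <- as.vector(outer(BASES, BASES, paste0))
  cl[substr(cl, 1, 1) != substr(cl, 2, 2)]
}

class_ref <- function(class) substr(class, 1, 1)
class_obs <- function(class) substr(class, 2, 2)

check_class <- function(class) {
  if (!is.character(class) || length(class) != 1L ||
      !(class %in% mismatch_classes())) {
    stop("mismatch class must be one of: ",
         paste(mismatch_classes(), collapse = ", "), call. = FALSE)
  }
  class
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# seed the RNG for the duration of the calling function, then restore
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  expr <- if (!is.null(old)) {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  } else {
    quote(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  do.call(on.exit, list(expr, add = TRUE, after = TRUE), envir = envir)
  invisible(NULL)
}
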