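#' Temperature-softened softmax
#'
#' `softmax(z / T)` computed row-wise with the usual max-shift for
#' numerical stability. Large temperatures flatten the distribution toward
#' uniform; `T = 1` is the plain softmax.
#'
#' @param z numeric vector of logits, or a matrix (items x classes)
#' @param T temperature, finite and positive
#' @return probability vector/matrix of the same shape
#' @export
softened_softmax <- function(z, T = 1) {
  stopifnot(is.finite(T), T > 0)
  if (!all(is.finite(z))) stop("non-finite logits")
  if (is.matrix(z)) {
    s <- z / T
    s <- s - apply(s, 1, max)
    e <- exp(s)
    e / rowSums(e)
  } else {
    s <- z / T
    e <- exp(s - max(s))
    e / sum(e)
  }
}

#' Kullback-Leibler divergence
#'
#' `KL(P || Q) = sum_i P(i) log(P(i) / Q(i))` in nats, with the
#' `0 * log 0 = 0` convention. Errors when `Q` lacks support where `P` has
#' mass, or when either argument is not a probability vector (components
#' must be non-negative and sum to 1 within 1e-9).
#'
#' @param P,Q probability vectors of equal length
#' @return divergence in nats (non-negative; 0 iff `P == Q`)
#' @export
kl_divergence <- function(P, Q) {
  stopifnot(length(P) == length(Q), all(P >= 0), all(Q >= 0),
            abs(sum(P) - 1) < 1e-9, abs(sum(Q) - 1) < 1e-9)
  if (any(Q == 0 & P > 0)) stop("support violation: Q(i)=0 where P(i)>0")
  i <- P > 0
  sum(P[i] * log(P[i] / Q[i]))
}

#' Temperature-scaled distillation loss
#'
#' The knowledge-distillation objective
#' `L = KL(softmax(z_t / T) || softmax(z_s / T)) * T^2`, averaged over the
#' items of a batch. The `T^2` factor keeps gradient magnitudes comparable
#' across temperatures. Zero exactly when the student logits equal the
#' teacher logits up to a per-item additive constant (softmax shift
#' invariance).
#'
#' @param z_t,z_s teacher and student logits, vectors or matrices of equal
#'   shape (items x classes)
#' @param T temperature
#' @return non-negative scalar loss
#' @export
distillation_loss <- function(z_t, z_s, T = 1) {
  if (!is.matrix(z_t)) z_t <- matrix(z_t, nrow = 1)
  if (!is.matrix(z_s)) z_s <- matrix(z_s, nrow = 1)
  if (!all(dim(z_t) == dim(z_s))) stop("teacher/student logit shape mismatch")
  P <- softened_softmax(z_t, T)
  Q <- softened_softmax(z_s, T)
  per_item <- vapply(seq_len(nrow(P)), function(i)
    kl_divergence(P[i, ], Q[i, ]), numeric(1))
  mean(per_item) * T^2
}

# ---------------------------------------------------------------------------
# Toy feed-forward classifiers (tanh hidden layers, linear logits)

#' Toy multilayer perceptron
#'
#' Small feed-forward classifier used to exercise the distillation kernel:
#' tanh hidden layers, linear output logits. `mlp_init()` draws Gaussian
#' weights; `mlp_forward()` returns the logit matrix;
#' `mlp_param_count()` the number of parameters.
#'
#' @param dims layer widths `c(input, hidden..., classes)`
#' @param seed integer seed
#' @param sd weight standard deviation
#' @return `mlp_init`: an `orqa_mlp` (list of layers, each `W` (out x in)
#'   and `b`)
#' @export
mlp_init <- function(dims, seed = 1, sd = 1.0) {
  stopifnot(length(dims) >= 2, all(dims >= 1))
  old <- .Random.seed_safe()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  layers <- lapply(seq_len(length(dims) - 1L), function(l) {
    list(W = matrix(stats::rnorm(dims[l + 1] * dims[l], 0,
                                 sd / sqrt(dims[l])),
                    nrow = dims[l + 1]),
         b = stats::rnorm(dims[l + 1], 0, 0.1))
  })
  structure(list(layers = layers, dims = as.integer(dims)),
            class = "orqa_mlp")
}

#' @rdname mlp_init
#' @param model an `orqa_mlp`
#' @param X input matrix (items x input dim)
#' @export
mlp_forward <- function(model, X) {
  H <- X
  nl <- length(model$layers)
  for (l in seq_len(nl)) {
    Z <- H %*% t(model$layers[[l]]$W) +
      matrix(model$layers[[l]]$b, nrow(H), length(model$layers[[l]]$b),
             byrow = TRUE)
    H <- if (l < nl) tanh(Z) else Z
  }
  H
}

#' @rdname mlp_init
#' @export
mlp_param_count <- function(model) {
  sum(vapply(model$layers, function(l) length(l$W) + length(l$b),
             numeric(1)))
}

#' Top-left weight-crop student initialization
#'
#' Initializes a smaller student from a teacher by taking the leading
#' (top-left) submatrix of every teacher weight matrix and the leading
#' entries of every bias, preserving a portion of the learned
#' representations. Cropping to the teacher's own dimensions is the
#' identity, and cropping twice equals a single crop to the smaller size.
#'
#' @param teacher an `orqa_mlp`
#' @param student_dims layer widths of the student; each must not exceed
#'   the corresponding teacher width (same number of layers)
#' @return an `orqa_mlp` with cropped weights
#' @export
crop_initialize <- function(teacher, student_dims) {
  stopifnot(inherits(teacher, "orqa_mlp"),
            length(student_dims) == length(teacher$dims))
  if (any(student_dims > teacher$dims))
    stop("student dimension exceeds teacher dimension")
  layers <- lapply(seq_along(teacher$layers), function(l) {
    W <- teacher$layers[[l]]$W
    b <- teacher$layers[[l]]$b
    list(W = W[seq_len(student_dims[l + 1]), seq_len(student_dims[l]),
               drop = FALSE],
         b = b[seq_len(student_dims[l + 1])])
  })
  structure(list(layers = layers, dims = as.integer(student_dims)),
            class = "orqa_mlp")
}

#' Synthetic Gaussian-mixture input generator
#'
#' Returns a closure drawing `n` points from a fixed mixture of Gaussian
#' clusters in the input space; used as the transfer set for toy
#' distillation.
#'
#' @param dim input dimension
#' @param n_clusters number of mixture components
#' @param seed seed fixing the component centers
#' @return `function(n, seed)` producing an `n x dim` matrix
#' @export
gaussian_mixture_gen <- function(dim = 4, n_clusters = 3, seed = 1) {
  old <- .Random.seed_safe()
  set.seed(seed)
  centers <- matrix(stats::rnorm(n_clusters * dim, 0, 2), nrow = n_clusters)
  .Random.seed_restore(old)
  function(n, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    comp <- sample.int(n_clusters, n, replace = TRUE)
    centers[comp, , drop = FALSE] +
      matrix(stats::rnorm(n * dim, 0, 1), nrow = n)
  }
}

# One SGD step of the distillation loss for an MLP; returns updated model
# and the batch loss. Gradient of mean_i KL(p_i||q_i)*T^2 wrt student
# logits is (T/n) (Q - P).
distill_step <- function(student, teacher_logits, X, T, lr) {
  nl <- length(student$layers)
  acts <- vector("list", nl + 1L)
  acts[[1]] <- X
  for (l in seq_len(nl)) {
    Z <- acts[[l]] %*% t(student$layers[[l]]$W) +
      matrix(student$layers[[l]]$b, nrow(X),
             length(student$layers[[l]]$b), byrow = TRUE)
    acts[[l + 1L]] <- if (l < nl) tanh(Z) else Z
  }
  P <- softened_softmax(teacher_logits, T)
  Q <- softened_softmax(acts[[nl + 1L]], T)
  loss <- mean(rowSums(ifelse(P > 0, P * log(P / Q), 0))) * T^2
  if (!is.finite(loss)) return(list(model = student, loss = loss))
  delta <- (T / nrow(X)) * (Q - P)
  for (l in rev(seq_len(nl))) {
    gW <- t(delta) %*% acts[[l]]
    gb <- colSums(delta)
    if (l > 1L) {
      dH <- delta %*% student$layers[[l]]$W
      delta <- dH * (1 - acts[[l]]^2)
    }
    student$layers[[l]]$W <- student$layers[[l]]$W - lr * gW
    student$layers[[l]]$b <- student$layers[[l]]$b - lr * gb
  }
  list(model = student, loss = loss)
}

#' Progressive distillation with shrinking students
#'
#' Distills a teacher into a sequence of progressively smaller students.
#' The first student is initialized by top-left weight crop from the
#' teacher, each subsequent student by crop from its trained predecessor,
#' and every student minimizes the temperature-scaled distillation loss on
#' synthetic inputs by stochastic gradient descent. Hidden dimensions must
#' be non-increasing along the schedule.
#'
#' @param teacher an `orqa_mlp`
#' @param schedule list of student layer-width vectors (or a numeric
#'   vector of hidden widths for one-hidden-layer teachers), strictly
#'   compatible with the teacher's shape and non-increasing
#' @param data_gen `function(n)` producing input batches (see
#'   [gaussian_mixture_gen()])
#' @param steps SGD steps per student
#' @param seed integer seed
#' @param T distillation temperature
#' @param lr learning rate
#' @param batch_size batch size
#' @return list with `students` (list of `orqa_mlp`) and `traces` (list of
#'   per-step loss vectors); aborts if the loss diverges to non-finite
#' @export
progressive_distill <- function(teacher, schedule, data_gen, steps = 300,
                                seed = 1, T = 2, lr = 0.5, batch_size = 64) {
  stopifnot(inherits(teacher, "orqa_mlp"))
  if (is.numeric(schedule) && !is.list(schedule)) {
    stopifnot(length(teacher$dims) == 3)
    schedule <- lapply(schedule, function(h)
      c(teacher$dims[1], h, teacher$dims[3]))
  }
  dims_mat <- do.call(rbind, schedule)
  if (any(apply(dims_mat, 2, function(x) any(diff(x) > 0))))
    stop("schedule hidden dimensions must be non-increasing")
  old <- .Random.seed_safe()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  students <- vector("list", length(schedule))
  traces <- vector("list", length(schedule))
  prev <- teacher
  for (k in seq_along(schedule)) {
    student <- crop_initialize(prev, schedule[[k]])
    trace <- numeric(steps)
    for (s in seq_len(steps)) {
      X <- data_gen(batch_size)
      zt <- mlp_forward(teacher, X)
      st <- distill_step(student, zt, X, T, lr)
      if (!is.finite(st$loss))
        stop("distillation diverged (non-finite loss) at student ", k,
             ", step ", s)
      student <- st$model
      trace[s] <- st$loss
    }
    students[[k]] <- student
    traces[[k]] <- trace
    prev <- student
  }
  list(students = students, traces = traces)
}

#' Argmax agreement between teacher and student
#'
#' Fraction of inputs on which student and teacher predict the same class.
#'
#' @param teacher,student `orqa_mlp` models
#' @param X evaluation inputs
#' @return agreement in `[0, 1]`
#' @export
argmax_agreement <- function(teacher, student, X) {
  at <- max.col(mlp_forward(teacher, X), ties.method = "first")
  as <- max.col(mlp_forward(student, X), ties.method = "first")
  mean(at == as)
}
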