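#' Assemble the input block(s) for a model kind
#'
#' `Tab` uses the 15 structured features, `Txt` the text embedding, and
#' `TabTxt` their concatenation (tab block first).
#'
#' @param kind one of "Tab", "Txt", "TabTxt".
#' @param features a `patient_features` object.
#' @param ids optional subset of patients (rows).
#' @return numeric input matrix.
#' @export
assemble_inputs <- function(kind, features, ids = NULL) {
  if (!kind %in% c("Tab", "Txt", "TabTxt"))
    stop("unknown model kind: ", kind, call. = FALSE)
  rows <- if (is.null(ids)) seq_along(features$ids)
  else match(ids, features$ids)
  switch(kind,
         Tab = features$tab[rows, , drop = FALSE],
         Txt = features$txt[rows, , drop = FALSE],
         TabTxt = cbind(features$tab[rows, , drop = FALSE],
                        features$txt[rows, , drop = FALSE]))
}

bce_loss <- function(eta, y) {
  # numerically stable binary cross-entropy with logits:
  # softplus(eta) - y * eta
  sp <- ifelse(eta > 30, eta, log1p(exp(pmin(eta, 30))))
  mean(sp - y * eta)
}

#' Train a logistic risk model by Adam on binary cross-entropy
#'
#' Minimises mean BCE over shuffled mini-batches; after each epoch the
#' validation loss is evaluated, and training stops once it has failed to
#' improve for `patience` epochs (or at `max_epochs`). The weights from the
#' best validation epoch are returned. Deterministic given `seed`.
#'
#' @param x training input matrix (n x p).
#' @param y 0/1 training labels.
#' @param x_val,y_val validation inputs and labels (early stopping).
#' @param max_epochs epoch cap (default 300).
#' @param batch_size mini-batch size (default 64).
#' @param patience epochs without validation improvement before stopping
#'   (default 10); `Inf` disables early stopping.
#' @param lr Adam step size (default 1e-3).
#' @param beta1,beta2,eps Adam moment parameters.
#' @param l2 optional ridge penalty on the weights (default 0).
#' @param seed integer seed for shuffling and initialisation.
#' @param kind optional label stored on the model.
#' @return a `risk_model`: list(kind, w, b, best_epoch, epochs_run,
#'   val_loss, history).
#' @export
train_lr <- function(x, y, x_val, y_val, max_epochs = 300L, batch_size = 64L,
                     patience = 10L, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, l2 = 0, seed = 1L, kind = NULL) {
  x <- as.matrix(x); x_val <- as.matrix(x_val)
  y <- as.numeric(y); y_val <- as.numeric(y_val)
  if (length(unique(y)) < 2L || length(unique(y_val)) < 2L)
    stop("training and validation parts must each contain both classes",
         call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(x_val)))
    stop("inputs contain non-finite values", call. = FALSE)
  n <- nrow(x); p <- ncol(x)

  with_seed(seed, {
    w <- numeric(p); b <- 0
    mw <- vw <- numeric(p); mb <- vb <- 0
    step <- 0L
    best <- list(loss = Inf, w = w, b = b, epoch = 0L)
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0))
    stall <- 0L
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        bi <- ord[start:min(start + batch_size - 1L, n)]
        xb <- x[bi, , drop = FALSE]
        yb <- y[bi]
        eta <- drop(xb %*% w) + b
        r <- stats::plogis(eta) - yb
        gw <- drop(crossprod(xb, r)) / length(bi) + l2 * w
        gb <- mean(r)
        step <- step + 1L
        mw <- beta1 * mw + (1 - beta1) * gw
        vw <- beta2 * vw + (1 - beta2) * gw^2
        mb <- beta1 * mb + (1 - beta1) * gb
        vb <- beta2 * vb + (1 - beta2) * gb^2
        c1 <- 1 - beta1^step; c2 <- 1 - beta2^step
        w <- w - lr * (mw / c1) / (sqrt(vw / c2) + eps)
        b <- b - lr * (mb / c1) / (sqrt(vb / c2) + eps)
      }
      tl <- bce_loss(drop(x %*% w) + b, y)
      vl <- bce_loss(drop(x_val %*% w) + b, y_val)
      history <- rbind(history,
                       data.frame(epoch = epoch, train_loss = tl, val_loss = vl))
      if (vl < best$loss) {
        best <- list(loss = vl, w = w, b = b, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) break
      }
    }
  })
  out <- list(kind = kind, w = best$w, b = best$b, best_epoch = best$epoch,
              epochs_run = nrow(history), val_loss = best$loss,
              history = history, seed = as.integer(seed))
  class(out) <- "risk_model"
  out
}

#' Predicted probability of a risk model
#'
#' @param object a `risk_model`.
#' @param newdata input matrix or vector matching the model dimension.
#' @param ... unused.
#' @return probabilities in (0, 1).
#' @export
predict.risk_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  if (ncol(newdata) != length(object$w))
    stop(sprintf("input has %d columns; model expects %d",
                 ncol(newdata), length(object$w)), call. = FALSE)
  stats::plogis(drop(newdata %*% object$w) + object$b)
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model%s> p = %d, best epoch %d/%d, val BCE %.5f\n",
              if (is.null(x$kind)) "" else paste0(" ", x$kind),
              length(x$w), x$best_epoch, x$epochs_run, x$val_loss))
  invisible(x)
}

#' Train one of the three risk models on a feature set
#'
#' Convenience wrapper: assembles the kind's input blocks for the train and
#' validation parts and calls [train_lr()]. The embedding itself is never
#' touched — only the logistic layer is trained.
#'
#' @param kind "Tab", "Txt" or "TabTxt".
#' @param features a `patient_features` object (with `part` assignments).
#' @param ... passed to [train_lr()].
#' @param seed integer seed.
#' @return a `risk_model` with `kind` set.
#' @export
fit_risk_model <- function(kind, features, seed = 1L, ...) {
  tr <- features$part == "train"
  va <- features$part == "validation"
  train_lr(assemble_inputs(kind, features, features$ids[tr]),
           features$label[tr],
           assemble_inputs(kind, features, features$ids[va]),
           features$label[va],
           seed = seed, kind = kind, ...)
}

#' Persist a risk model as JSON
#'
#' @param model a `risk_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_risk_model <- function(model, path) {
  jsonlite::write_json(
    list(kind = model$kind, w = model$w, b = model$b,
         best_epoch = model$best_epoch, epochs_run = model$epochs_run,
         val_loss = model$val_loss, seed = model$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a risk model written by [write_risk_model()]
#'
#' @param path JSON file.
#' @return a `risk_model`.
#' @export
read_risk_model <- function(path) {
  m <- jsonlite::fromJSON(path)
  out <- list(kind = m$kind, w = as.numeric(m$w), b = m$b,
              best_epoch = m$best_epoch, epochs_run = m$epochs_run,
              val_loss = m$val_loss, seed = m$seed, history = NULL)
  class(out) <- "risk_model"
  out
}
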