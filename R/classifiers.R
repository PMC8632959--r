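# The five classifier families used for wrapper fitness and final evaluation.
# Each fit standardizes features on the training fold and applies the training
# statistics to the validation fold (no leakage).

classifier_names <- c("lr", "dt", "knn", "svm", "rf")

default_classifier_params <- function() {
  list(
    lr = list(),                    # unpenalized logistic regression (glm.fit)
    dt = list(),                    # rpart defaults
    knn = list(k = 5),
    svm = list(cost = 1),           # RBF kernel
    rf = list(ntree = 100)
  )
}

standardize_pair <- function(x_train, x_test) {
  mu <- colMeans(x_train)
  sig <- apply(x_train, 2, sd)
  sig[sig == 0] <- 1
  list(
    train = sweep(sweep(x_train, 2, mu), 2, sig, "/"),
    test = sweep(sweep(x_test, 2, mu), 2, sig, "/")
  )
}

# returns predicted factor labels for x_test
fit_predict <- function(classifier, x_train, y_train, x_test, params = list()) {
  classifier <- match.arg(classifier, classifier_names)
  p <- modifyList(default_classifier_params()[[classifier]], params)
  lv <- levels(y_train)
  st <- standardize_pair(as.matrix(x_train), as.matrix(x_test))
  pred <- switch(
    classifier,
    lr = {
      fit <- suppressWarnings(
        stats::glm.fit(cbind(1, st$train), as.integer(y_train) - 1L,
                       family = stats::binomial())
      )
      eta <- cbind(1, st$test) %*% fit$coefficients
      lv[as.integer(eta > 0) + 1L]
    },
    dt = {
      df_tr <- data.frame(st$train, .y = y_train, check.names = FALSE)
      fit <- rpart::rpart(.y ~ ., data = df_tr, method = "class")
      as.character(predict(fit, data.frame(st$test, check.names = FALSE),
                           type = "class"))
    },
    knn = {
      as.character(class::knn(st$train, st$test, y_train, k = p$k))
    },
    svm = {
      fit <- e1071::svm(st$train, y_train, kernel = "radial", cost = p$cost,
                        scale = FALSE)
      as.character(predict(fit, st$test))
    },
    rf = {
      fit <- randomForest::randomForest(st$train, y_train, ntree = p$ntree)
      as.character(predict(fit, st$test))
    }
  )
  factor(pred, levels = lv)
}
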