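# Link functions for the three ZIB regression parts.
# p and mu live on (0,1): logit, probit, loglog.
# phi lives on (0,Inf): log, sqrt.

.UNIT_LINKS <- c("logit", "probit", "loglog")
.POS_LINKS <- c("log", "sqrt")

# loglog(p) = -log(-log(p)); increasing on (0,1), range R
.loglogLink <- function() {
  structure(list(
    linkfun = function(mu) -log(-log(mu)),
    linkinv = function(eta) {
      p <- exp(-exp(-eta))
      pmin(pmax(p, .Machine$double.eps), 1 - .Machine$double.eps)
    },
    mu.eta = function(eta) {
      pmax(exp(-exp(-eta)) * exp(-eta), .Machine$double.eps)
    },
    valideta = function(eta) TRUE,
    name = "loglog"
  ), class = "link-glm")
}

.unitLink <- function(name) {
  name <- match.arg(name, .UNIT_LINKS)
  if (name == "loglog") .loglogLink() else stats::make.link(name)
}

.posLink <- function(name) {
  name <- match.arg(name, .POS_LINKS)
  if (name == "log") {
    list(linkfun = log, linkinv = exp, mu.eta = exp, name = "log")
  } else {
    list(linkfun = sqrt, linkinv = function(eta) eta^2,
         mu.eta = function(eta) 2 * eta, name = "sqrt")
  }
}
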