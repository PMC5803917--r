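"""Exact rational-arithmetic oracle for the 2x2 over-representation test.

Enumerates every contingency table (a, b, c, d) with a + b + c + d <= MAX_N
and computes, with exact integer arithmetic only:

  * the point probability of the observed table from the factorial form
        (a+b)! (c+d)! (a+c)! (b+d)! / (a! b! c! d! n!)
  * the one-sided (over-representation) tail p-value as the exact rational
    suffix sum of binomial-coefficient products
        sum_{k >= a} C(D, k) C(n-D, K-k) / C(n, K)
    with margins D = a + b and K = a + c held fixed,

cross-checks that the two point-probability routes agree exactly as
integers, and writes one row per table:

    n  K  D  a  p_tail  p_point

where the floats are the correctly rounded doubles of the exact rationals.

Usage: python exact_hypergeom_oracle.py MAX_N OUT_TSV
"""

import sys
from fractions import Fraction
from math import comb, factorial


def main(max_n: int, out_path: str) -> None:
    with open(out_path, "w") as out:
        out.write("n\tK\tD\ta\tp_tail\tp_point\n")
        for n in range(1, max_n + 1):
            fact_n = factorial(n)
            for K in range(0, n + 1):
                denom = comb(n, K)
                for D in range(0, n + 1):
                    kmin = max(0, K + D - n)
                    kmax = min(K, D)
                    terms = [comb(D, k) * comb(n - D, K - k)
                             for k in range(kmin, kmax + 1)]
                    # suffix[i] = sum of terms[i:]
                    suffix = list(terms)
                    for i in range(len(suffix) - 2, -1, -1):
                        suffix[i] += suffix[i + 1]
                    assert suffix[0] == denom  # total mass check
                    for i, a in enumerate(range(kmin, kmax + 1)):
                        b, c = D - a, K - a
                        d = n - a - b - c
                        # Eq.-style factorial form, exact integers
                        point_num = (factorial(a + b) * factorial(c + d)
                                     * factorial(a + c) * factorial(b + d))
                        point_den = (factorial(a) * factorial(b) * factorial(c)
                                     * factorial(d) * fact_n)
                        # same rational as the binomial-product route
                        assert point_num * denom == terms[i] * point_den
                        p_tail = float(Fraction(suffix[i], denom))
                        p_point = float(Fraction(point_num, point_den))
                        out.write(f"{n}\t{K}\t{D}\t{a}\t{p_tail!r}\t{p_point!r}\n")


if __name__ == "__main__":
    main(int(sys.argv[1]), sys.argv[2])
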