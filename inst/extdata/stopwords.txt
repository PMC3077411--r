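the
and
for
are
was
were
with
that
this
these
those
from
have
has
had
not
but
can
could
may
might
will
would
should
its
his
her
their
our
your
been
being
which
into
than
then
also
more
most
some
such
only
other
both
each
between
about
after
before
during
under
over
all
any
one
two
three
when
where
while
who
whom
how
what
why
does
did
done
using
used
use
via
per
here
there
well
however
therefore
thus
among
within
without
upon
due
both
very
much
many
few
several
show
shown
showed
shows
study
studies
result
results
suggest
suggests
suggested
indicate
indicates
indicated
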