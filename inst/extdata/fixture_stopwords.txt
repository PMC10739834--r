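a
an
the
and
or
but
if
of
to
in
on
at
for
with
is
am
are
was
were
be
been
being
it
its
this
that
these
those
i
we
you
he
she
they
me
us
him
her
them
my
our
your
his
their
as
by
from
so
do
does
did
have
has
had
will
would
not
no
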