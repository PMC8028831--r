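code	name	operand	contract
a	nop-A	-	no-op; operand modifier (AX/IP) and label symbol
b	nop-B	-	no-op; operand modifier (BX/read head) and label symbol
c	nop-C	-	no-op; operand modifier (CX/write head) and label symbol
d	if-n-equ	?BX?	execute next instruction only if ?BX? != its complement register
e	if-less	?BX?	execute next instruction only if ?BX? < its complement register
f	if-label	label	execute next instruction only if the complement of the following label was just copied
g	mov-head	?IP?	move ?IP? to the flow head position
h	jmp-head	?IP?	advance ?IP? by CX positions (modulo memory size)
i	get-head	?IP?	CX <- position of ?IP?
j	set-flow	?CX?	flow head <- value of ?CX? (modulo memory size)
k	shift-r	?BX?	?BX? <- ?BX? >> 1
l	shift-l	?BX?	?BX? <- ?BX? << 1
m	inc	?BX?	?BX? <- ?BX? + 1
n	dec	?BX?	?BX? <- ?BX? - 1
o	push	?BX?	push ?BX? onto the active stack
p	pop	?BX?	pop the active stack into ?BX? (0 when empty)
q	swap-stk	-	toggle the active stack
r	swap	?BX?	swap ?BX? with its complement register
s	add	?BX?	?BX? <- BX + CX
t	sub	?BX?	?BX? <- BX - CX
u	nand	?BX?	?BX? <- bitwise NAND of BX and CX
v	h-copy	-	copy one instruction from the read head to the write head (may mutate); advance both
w	h-alloc	-	extend memory to 240 sites (nop-X filled); write head to site 120
x	h-divide	-	split off sites 120-239 as the offspring genome; reset parent state
y	IO	?BX?	output ?BX? for task checking, then load a fresh 5-bit input into ?BX?
z	h-search	label	find the complement of the following label; flow head to its start, BX=distance, CX=size; empty label: flow head to next site
A	nop-X	-	null instruction: no operation, not a label symbol
B	send-msg	-	send (BX, CX) to the faced neighbor
C	retrieve-msg	-	pop the oldest queued message into (BX, CX); no-op when empty
D	bcast1	-	send (BX, CX) to all eight neighbors
E	rotate-left-one	-	rotate facing one step anticlockwise
F	rotate-right-one	-	rotate facing one step clockwise
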